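# SYNTHETIC name-gender dictionary (not the gender-guesser nam_dict).
# Small curated list in the same two-column format the loader accepts for any
# substitute dictionary: name <TAB> label, labels in
# {male, female, mostly_male, mostly_female, androgynous}.
# Names absent from the dictionary resolve to "unknown" at lookup time.
name	label
james	male
john	male
robert	male
michael	male
william	male
david	male
richard	male
joseph	male
thomas	male
charles	male
christopher	male
daniel	male
matthew	male
anthony	male
mark	male
donald	male
steven	male
paul	male
andrew	male
joshua	male
kenneth	male
kevin	male
brian	male
george	male
edward	male
ronald	male
timothy	male
jason	male
jeffrey	male
ryan	male
jacob	male
gary	male
nicholas	male
eric	male
jonathan	male
stephen	male
larry	male
justin	male
scott	male
brandon	male
benjamin	male
samuel	male
gregory	male
frank	male
alexander	male
raymond	male
patrick	male
jack	male
dennis	male
jerry	male
pedro	male
juan	male
carlos	male
luigi	male
henrik	male
dmitri	male
kenji	male
rajesh	male
omar	male
kwame	male
mary	female
patricia	female
jennifer	female
linda	female
elizabeth	female
barbara	female
susan	female
jessica	female
sarah	female
karen	female
nancy	female
lisa	female
betty	female
margaret	female
sandra	female
ashley	female
kimberly	female
emily	female
donna	female
michelle	female
dorothy	female
carol	female
amanda	female
melissa	female
deborah	female
stephanie	female
rebecca	female
sharon	female
laura	female
cynthia	female
kathleen	female
amy	female
shirley	female
angela	female
helen	female
anna	female
brenda	female
pamela	female
nicole	female
emma	female
samantha	female
katherine	female
christine	female
debra	female
rachel	female
catherine	female
carolyn	female
janet	female
ruth	female
maria	female
ingrid	female
yuki	female
priya	female
fatima	female
chiara	female
amara	female
sofia	female
olga	female
mei	female
aisha	female
stacy	mostly_male
angel	mostly_male
jean	mostly_male
marion	mostly_male
leslie	mostly_male
francis	mostly_male
tracy	mostly_male
noel	mostly_male
sasha	mostly_male
lior	mostly_male
andrea	mostly_female
shannon	mostly_female
lauren	mostly_female
dana	mostly_female
carmen	mostly_female
whitney	mostly_female
shelby	mostly_female
courtney	mostly_female
ariel	mostly_female
eden	mostly_female
alex	androgynous
taylor	androgynous
jordan	androgynous
casey	androgynous
riley	androgynous
morgan	androgynous
avery	androgynous
quinn	androgynous
skyler	androgynous
rowan	androgynous
kerry	androgynous
devon	androgynous
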