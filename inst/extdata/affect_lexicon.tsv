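word	polarity	subjectivity
ecstatic	0.95	1.00
euphoric	0.95	1.00
overjoyed	0.90	1.00
blissful	0.90	0.95
exhilarating	0.90	0.95
magnificent	0.90	0.90
breathtaking	0.90	0.90
sublime	0.85	0.90
glorious	0.85	0.90
marvelous	0.85	0.90
superb	0.85	0.85
dazzling	0.80	0.85
stunning	0.80	0.85
exquisite	0.80	0.85
wonderful	0.80	0.90
magical	0.80	0.85
enchanting	0.75	0.85
mesmerizing	0.75	0.85
radiant	0.75	0.80
captivating	0.75	0.80
delightful	0.75	0.85
splendid	0.75	0.80
joyous	0.75	0.90
thrilling	0.70	0.85
inspiring	0.70	0.80
uplifting	0.70	0.80
beautiful	0.70	0.85
adorable	0.70	0.85
heavenly	0.70	0.85
brilliant	0.70	0.80
happy	0.65	0.90
joyful	0.65	0.90
delighted	0.65	0.90
cheerful	0.60	0.85
luminous	0.60	0.70
graceful	0.60	0.75
lovely	0.60	0.80
elegant	0.55	0.70
serene	0.55	0.70
hopeful	0.55	0.80
tender	0.50	0.75
vibrant	0.50	0.70
charming	0.50	0.75
peaceful	0.50	0.70
harmonious	0.50	0.65
soothing	0.45	0.70
playful	0.45	0.70
warm	0.45	0.65
lively	0.45	0.65
dreamy	0.40	0.75
gentle	0.40	0.65
calming	0.40	0.65
inviting	0.40	0.65
expressive	0.35	0.70
pleasing	0.35	0.70
rich	0.35	0.55
pleasant	0.35	0.65
vivid	0.30	0.55
bright	0.30	0.50
admirable	0.30	0.70
colorful	0.25	0.45
fresh	0.25	0.50
engaging	0.25	0.60
intriguing	0.20	0.60
interesting	0.20	0.55
curious	0.15	0.60
delicate	0.15	0.50
soft	0.15	0.40
dynamic	0.15	0.45
bold	0.10	0.50
striking	0.20	0.70
intense	0.05	0.85
emotional	0.05	0.90
moving	0.50	0.85
touching	0.55	0.85
powerful	0.30	0.70
dramatic	0.05	0.70
overwhelming	-0.05	0.90
mysterious	0.05	0.65
surreal	0.05	0.70
nostalgic	0.15	0.80
wistful	-0.05	0.80
bittersweet	0.00	0.85
ambiguous	-0.05	0.55
symbolic	0.05	0.40
abstract	0.00	0.35
figurative	0.00	0.30
detailed	0.10	0.30
textured	0.05	0.30
layered	0.05	0.35
realistic	0.10	0.30
geometric	0.00	0.20
monochrome	0.00	0.15
muted	-0.05	0.35
minimal	0.00	0.30
ornate	0.05	0.40
classical	0.05	0.25
modern	0.05	0.25
historic	0.05	0.20
luminescent	0.20	0.40
shadowy	-0.15	0.45
hazy	-0.10	0.40
faded	-0.15	0.40
pale	-0.10	0.35
plain	-0.15	0.40
dull	-0.30	0.55
bland	-0.30	0.60
boring	-0.40	0.75
tedious	-0.40	0.70
uninspired	-0.35	0.70
lifeless	-0.45	0.65
flat	-0.20	0.45
heavy	-0.20	0.45
cold	-0.25	0.50
distant	-0.25	0.50
detached	-0.25	0.55
odd	-0.20	0.55
strange	-0.20	0.55
confusing	-0.30	0.60
cluttered	-0.30	0.55
chaotic	-0.45	0.60
messy	-0.35	0.55
unbalanced	-0.30	0.50
uneasy	-0.40	0.70
restless	-0.35	0.65
tense	-0.40	0.65
anxious	-0.50	0.80
worried	-0.50	0.80
nervous	-0.45	0.75
fearful	-0.55	0.80
frightening	-0.60	0.80
unsettling	-0.50	0.75
disturbing	-0.55	0.75
ominous	-0.50	0.70
eerie	-0.45	0.70
haunting	-0.35	0.75
melancholic	-0.50	0.80
melancholy	-0.50	0.80
somber	-0.45	0.70
gloomy	-0.55	0.75
bleak	-0.60	0.70
dreary	-0.55	0.70
mournful	-0.60	0.80
sorrowful	-0.65	0.85
sad	-0.60	0.85
unhappy	-0.60	0.85
lonely	-0.55	0.80
isolated	-0.45	0.65
desolate	-0.60	0.70
grim	-0.60	0.70
dark	-0.30	0.50
harsh	-0.45	0.60
bitter	-0.50	0.70
painful	-0.60	0.80
distressing	-0.60	0.80
depressing	-0.65	0.80
oppressive	-0.60	0.70
suffocating	-0.65	0.75
menacing	-0.60	0.70
sinister	-0.60	0.70
ugly	-0.65	0.80
unpleasant	-0.55	0.75
disgusting	-0.80	0.90
repulsive	-0.80	0.90
revolting	-0.80	0.90
hideous	-0.80	0.85
ghastly	-0.80	0.85
dreadful	-0.85	0.90
horrible	-0.85	0.95
terrible	-0.85	0.95
awful	-0.85	0.95
horrifying	-0.90	0.95
terrifying	-0.90	0.95
nightmarish	-0.90	0.95
agonizing	-0.90	0.95
devastating	-0.90	0.90
despairing	-0.90	0.95
anguished	-0.90	0.95
tormented	-0.85	0.90
hopeless	-0.85	0.95
miserable	-0.80	0.95
wretched	-0.80	0.90
tragic	-0.70	0.85
heartbreaking	-0.75	0.90
crushing	-0.70	0.80
alarming	-0.55	0.70
shocking	-0.40	0.75
startling	-0.25	0.65
jarring	-0.35	0.60
garish	-0.40	0.60
loud	-0.15	0.45
quiet	0.10	0.40
still	0.05	0.35
airy	0.20	0.45
breezy	0.25	0.50
sunny	0.40	0.55
golden	0.30	0.45
glowing	0.40	0.55
sparkling	0.45	0.55
shimmering	0.35	0.50
crisp	0.25	0.45
smooth	0.25	0.40
balanced	0.20	0.40
refined	0.30	0.50
masterful	0.60	0.75
skillful	0.45	0.60
impressive	0.55	0.75
remarkable	0.50	0.75
memorable	0.45	0.70
evocative	0.30	0.70
poignant	0.10	0.80
profound	0.35	0.75
thoughtful	0.35	0.65
contemplative	0.20	0.60
meditative	0.25	0.60
spiritual	0.25	0.65
sacred	0.30	0.55
romantic	0.50	0.75
passionate	0.55	0.85
sensual	0.35	0.75
whimsical	0.35	0.65
amusing	0.45	0.70
funny	0.50	0.75
humorous	0.45	0.70
witty	0.45	0.70
clever	0.40	0.65
energetic	0.40	0.60
exciting	0.60	0.80
festive	0.50	0.65
triumphant	0.65	0.80
proud	0.45	0.75
grateful	0.60	0.85
content	0.45	0.75
satisfied	0.50	0.80
comforting	0.50	0.70
reassuring	0.45	0.70
welcoming	0.45	0.65
friendly	0.45	0.65
kind	0.50	0.70
innocent	0.30	0.60
pure	0.35	0.55
noble	0.40	0.60
majestic	0.60	0.70
grand	0.45	0.60
epic	0.40	0.60
timeless	0.35	0.55
iconic	0.30	0.55
ordinary	-0.10	0.45
mediocre	-0.35	0.70
forgettable	-0.30	0.65
disappointing	-0.55	0.80
frustrating	-0.50	0.80
annoying	-0.50	0.80
irritating	-0.50	0.75
unnerving	-0.45	0.70
humbling	0.20	0.65
humble	0.25	0.60
modest	0.15	0.50
raw	-0.05	0.55
gritty	-0.15	0.55
brooding	-0.30	0.65
moody	-0.20	0.60
stormy	-0.30	0.50
turbulent	-0.35	0.55
violent	-0.60	0.70
aggressive	-0.45	0.65
angry	-0.60	0.85
furious	-0.75	0.90
enraged	-0.80	0.90
hostile	-0.55	0.70
cruel	-0.70	0.80
brutal	-0.65	0.75
savage	-0.55	0.70
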