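abandoned	-2
adore	3
afraid	-2
agony	-3
alone	-2
amazing	4
angry	-3
annoyed	-2
anxious	-2
awesome	4
awful	-3
bad	-3
beautiful	3
best	3
bitter	-2
blessed	3
bored	-2
brave	2
broken	-1
calm	2
celebrate	3
cheer	2
comfort	2
cool	1
crap	-3
crazy	-2
cried	-2
cry	-1
cure	2
damn	-4
dead	-3
depressed	-2
despair	-3
die	-3
disappointed	-2
distress	-3
dread	-2
dying	-3
eager	2
ease	2
enjoy	2
excellent	3
excited	3
excitement	3
fail	-2
fear	-2
fever	-2
fine	2
fun	4
funny	4
glad	3
gloomy	-2
good	3
grateful	3
great	3
grief	-2
happy	3
hate	-3
heartbroken	-3
hell	-4
hope	2
hopeful	2
horrible	-3
hug	2
hurt	-2
ill	-2
injured	-2
insomnia	-2
inspired	2
joy	3
kill	-3
kind	2
like	2
lol	3
lonely	-2
lose	-3
loss	-3
lost	-3
love	3
loved	3
lovely	3
lucky	3
mad	-3
miserable	-3
misery	-2
miss	-2
nervous	-2
nice	3
numb	-1
pain	-2
painful	-2
panic	-3
peace	2
perfect	3
pleasure	3
poor	-2
pretty	1
problem	-2
proud	2
regret	-2
relax	2
relief	1
relieved	2
sad	-2
scared	-2
sick	-2
smile	2
sore	-1
sorrow	-2
sorry	-1
strong	2
struggle	-2
stress	-1
stressed	-2
stupid	-2
suffer	-2
suffering	-2
super	3
sweet	2
terrible	-3
thank	2
thanks	2
tired	-2
torture	-4
tough	-2
trouble	-2
ugly	-3
unbearable	-2
upset	-2
weak	-2
weary	-2
welcome	2
win	4
winner	4
wonderful	4
worry	-3
worse	-3
worst	-3
wow	4
wrong	-2
yeah	1
yummy	3
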