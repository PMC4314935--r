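# Default 62-mammal roster for the human-lineage sequon-gain screen.
# One species per line: id <TAB> group <TAB> comma-separated aliases.
# group is the innermost clade on the human-lineage ladder
# (hum hac aga gra ape cat sim pri eua) or an outgroup group
# (gli lau afr xen mar mon).  Aliases are genome-assembly codes.
human	hum	hg19,hg38
chimpanzee	hac	panTro4
gorilla	aga	gorGor3
orangutan	gra	ponAbe2
gibbon	ape	nomLeu3
rhesus_macaque	cat	rheMac3
crab_eating_macaque	cat	macFas5
baboon	cat	papHam1,papAnu2
green_monkey	cat	chlSab1,chlSab2
marmoset	sim	calJac3
squirrel_monkey	sim	saiBol1
bushbaby	pri	otoGar3
treeshrew	eua	tupChi1,tupBel1
squirrel	gli	speTri2
lesser_egyptian_jerboa	gli	jacJac1
prairie_vole	gli	micOch1
chinese_hamster	gli	criGri1
golden_hamster	gli	mesAur1
mouse	gli	mm10,mm9
rat	gli	rn5,rn6
naked_mole_rat	gli	hetGla2
guinea_pig	gli	cavPor3
chinchilla	gli	chiLan1
brush_tailed_rat	gli	octDeg1
rabbit	gli	oryCun2
pika	gli	ochPri3
pig	lau	susScr3
alpaca	lau	vicPac2
bactrian_camel	lau	camFer1
dolphin	lau	turTru2
killer_whale	lau	orcOrc1
tibetan_antelope	lau	panHod1
cow	lau	bosTau7,bosTau8
sheep	lau	oviAri3
goat	lau	capHir1
horse	lau	equCab2
white_rhinoceros	lau	cerSim1
cat	lau	felCat5
dog	lau	canFam3
ferret	lau	musFur1
panda	lau	ailMel1
pacific_walrus	lau	odoRosDiv1
weddell_seal	lau	lepWed1
black_flying_fox	lau	pteAle1
megabat	lau	pteVam1
davids_myotis	lau	myoDav1
microbat	lau	myoLuc2
big_brown_bat	lau	eptFus1
hedgehog	lau	eriEur2
shrew	lau	sorAra2
star_nosed_mole	lau	conCri1
elephant	afr	loxAfr3
cape_elephant_shrew	afr	eleEdw1
manatee	afr	triMan1
cape_golden_mole	afr	chrAsi1
tenrec	afr	echTel2
aardvark	afr	oryAfe1
armadillo	xen	dasNov3
opossum	mar	monDom5
tasmanian_devil	mar	sarHar1
wallaby	mar	macEug2
platypus	mon	ornAna1
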