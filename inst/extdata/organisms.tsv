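name	genus	common_name
Manihot esculenta	Manihot	cassava
Dioscorea rotundata	Dioscorea	white yam
Dioscorea alata	Dioscorea	water yam
Musa acuminata	Musa	banana
Musa balbisiana	Musa	plantain ancestor
Ipomoea batatas	Ipomoea	sweetpotato
Solanum tuberosum	Solanum	potato
Solanum lycopersicum	Solanum	tomato
Solanum melongena	Solanum	eggplant
Zea mays	Zea	maize
Triticum aestivum	Triticum	bread wheat
Triticum durum	Triticum	durum wheat
Oryza sativa	Oryza	rice
Oryza glaberrima	Oryza	African rice
Hordeum vulgare	Hordeum	barley
Avena sativa	Avena	oat
Secale cereale	Secale	rye
Sorghum bicolor	Sorghum	sorghum
Pennisetum glaucum	Pennisetum	pearl millet
Eleusine coracana	Eleusine	finger millet
Setaria italica	Setaria	foxtail millet
Eragrostis tef	Eragrostis	tef
Glycine max	Glycine	soybean
Phaseolus vulgaris	Phaseolus	common bean
Phaseolus lunatus	Phaseolus	lima bean
Vigna unguiculata	Vigna	cowpea
Vigna radiata	Vigna	mung bean
Cajanus cajan	Cajanus	pigeonpea
Cicer arietinum	Cicer	chickpea
Lens culinaris	Lens	lentil
Pisum sativum	Pisum	pea
Vicia faba	Vicia	faba bean
Arachis hypogaea	Arachis	groundnut
Lupinus albus	Lupinus	white lupin
Medicago sativa	Medicago	alfalfa
Trifolium pratense	Trifolium	red clover
Gossypium hirsutum	Gossypium	upland cotton
Helianthus annuus	Helianthus	sunflower
Carthamus tinctorius	Carthamus	safflower
Brassica napus	Brassica	rapeseed
Brassica oleracea	Brassica	cabbage
Brassica rapa	Brassica	turnip
Raphanus sativus	Raphanus	radish
Sinapis alba	Sinapis	white mustard
Sesamum indicum	Sesamum	sesame
Ricinus communis	Ricinus	castor bean
Elaeis guineensis	Elaeis	oil palm
Cocos nucifera	Cocos	coconut
Olea europaea	Olea	olive
Saccharum officinarum	Saccharum	sugarcane
Beta vulgaris	Beta	sugar beet
Coffea arabica	Coffea	arabica coffee
Coffea canephora	Coffea	robusta coffee
Camellia sinensis	Camellia	tea
Theobroma cacao	Theobroma	cacao
Hevea brasiliensis	Hevea	rubber tree
Nicotiana tabacum	Nicotiana	tobacco
Capsicum annuum	Capsicum	pepper
Cucumis sativus	Cucumis	cucumber
Cucumis melo	Cucumis	melon
Citrullus lanatus	Citrullus	watermelon
Cucurbita pepo	Cucurbita	squash
Cucurbita maxima	Cucurbita	pumpkin
Abelmoschus esculentus	Abelmoschus	okra
Allium cepa	Allium	onion
Allium sativum	Allium	garlic
Daucus carota	Daucus	carrot
Lactuca sativa	Lactuca	lettuce
Spinacia oleracea	Spinacia	spinach
Apium graveolens	Apium	celery
Asparagus officinalis	Asparagus	asparagus
Fragaria x ananassa	Fragaria	strawberry
Rubus idaeus	Rubus	raspberry
Vaccinium corymbosum	Vaccinium	blueberry
Vitis vinifera	Vitis	grapevine
Malus domestica	Malus	apple
Pyrus communis	Pyrus	pear
Prunus persica	Prunus	peach
Prunus avium	Prunus	sweet cherry
Prunus dulcis	Prunus	almond
Prunus armeniaca	Prunus	apricot
Juglans regia	Juglans	walnut
Corylus avellana	Corylus	hazelnut
Castanea sativa	Castanea	chestnut
Anacardium occidentale	Anacardium	cashew
Mangifera indica	Mangifera	mango
Persea americana	Persea	avocado
Carica papaya	Carica	papaya
Ananas comosus	Ananas	pineapple
Psidium guajava	Psidium	guava
Citrus sinensis	Citrus	sweet orange
Citrus limon	Citrus	lemon
Citrus reticulata	Citrus	mandarin
Punica granatum	Punica	pomegranate
Ficus carica	Ficus	fig
Phoenix dactylifera	Phoenix	date palm
Colocasia esculenta	Colocasia	taro
Xanthosoma sagittifolium	Xanthosoma	cocoyam
Ensete ventricosum	Ensete	enset
Fagopyrum esculentum	Fagopyrum	buckwheat
Chenopodium quinoa	Chenopodium	quinoa
Amaranthus caudatus	Amaranthus	amaranth
Linum usitatissimum	Linum	flax
Cannabis sativa	Cannabis	hemp
Humulus lupulus	Humulus	hop
Saccharina latissima	Saccharina	sugar kelp
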