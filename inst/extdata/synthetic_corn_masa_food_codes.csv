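"food_code","description"
56205260,"Corn tortilla, plain"
56208080,"Corn tortilla, fried"
56254424,"Taco shell, corn"
56274398,"Tamale, plain"
56274742,"Tamale, with meat"
56308126,"Tamale, with chicken"
56313463,"Tostada shell, corn"
56385657,"Corn masa harina"
56438549,"Pupusa, cheese"
56448033,"Pupusa, bean"
56486752,"Gordita, corn masa"
56495899,"Sope, corn masa"
56525154,"Enchilada, cheese, corn tortilla"
56525229,"Enchilada, chicken, corn tortilla"
56539447,"Taco, beef, corn tortilla"
56540097,"Taco, chicken, corn tortilla"
56576659,"Taquito, corn tortilla"
56584213,"Quesadilla, corn tortilla"
56609955,"Chilaquiles"
56666204,"Atole, corn masa"
56672190,"Corn masa snack chip"
56721507,"Tortilla chip, corn masa"
56771768,"Nacho chips with cheese, corn masa"
56777846,"Huarache, corn masa"
56801030,"Empanada, corn masa"
56823843,"Corn masa dumpling"
56836967,"Menudo with corn masa"
56844792,"Pozole-style soup with masa"
56929792,"Corn masa porridge"
57021214,"Flauta, corn tortilla"
57064878,"Corn tortilla, plain, restaurant"
57103044,"Corn tortilla, fried, restaurant"
57105741,"Taco shell, corn, restaurant"
57210032,"Tamale, plain, restaurant"
57221685,"Tamale, with meat, restaurant"
57241154,"Tamale, with chicken, restaurant"
57244953,"Tostada shell, corn, restaurant"
57260925,"Corn masa harina, restaurant"
57284653,"Pupusa, cheese, restaurant"
57285370,"Pupusa, bean, restaurant"
57310216,"Gordita, corn masa, restaurant"
57311659,"Sope, corn masa, restaurant"
57322937,"Enchilada, cheese, corn tortilla, restaurant"
57328343,"Enchilada, chicken, corn tortilla, restaurant"
57354668,"Taco, beef, corn tortilla, restaurant"
57406559,"Taco, chicken, corn tortilla, restaurant"
57451080,"Taquito, corn tortilla, restaurant"
57454986,"Quesadilla, corn tortilla, restaurant"
57498337,"Chilaquiles, restaurant"
57550269,"Atole, corn masa, restaurant"
57640057,"Corn masa snack chip, restaurant"
57675504,"Tortilla chip, corn masa, restaurant"
57693179,"Nacho chips with cheese, corn masa, restaurant"
57741217,"Huarache, corn masa, restaurant"
57747421,"Empanada, corn masa, restaurant"
57774770,"Corn masa dumpling, restaurant"
57801883,"Menudo with corn masa, restaurant"
57834468,"Pozole-style soup with masa, restaurant"
57839550,"Corn masa porridge, restaurant"
57875121,"Flauta, corn tortilla, restaurant"
57917789,"Corn tortilla, plain, home recipe"
57927244,"Corn tortilla, fried, home recipe"
57937635,"Taco shell, corn, home recipe"
57981625,"Tamale, plain, home recipe"
57992196,"Tamale, with meat, home recipe"
57992629,"Tamale, with chicken, home recipe"
58014375,"Tostada shell, corn, home recipe"
58035023,"Corn masa harina, home recipe"
58071947,"Pupusa, cheese, home recipe"
58122610,"Pupusa, bean, home recipe"
58150943,"Gordita, corn masa, home recipe"
58204897,"Sope, corn masa, home recipe"
58218796,"Enchilada, cheese, corn tortilla, home recipe"
58235610,"Enchilada, chicken, corn tortilla, home recipe"
58310761,"Taco, beef, corn tortilla, home recipe"
58313252,"Taco, chicken, corn tortilla, home recipe"
58323002,"Taquito, corn tortilla, home recipe"
58359131,"Quesadilla, corn tortilla, home recipe"
58379707,"Chilaquiles, home recipe"
58381545,"Atole, corn masa, home recipe"
58438645,"Corn masa snack chip, home recipe"
58439447,"Tortilla chip, corn masa, home recipe"
58504108,"Nacho chips with cheese, corn masa, home recipe"
58523430,"Huarache, corn masa, home recipe"
58548600,"Empanada, corn masa, home recipe"
58583406,"Corn masa dumpling, home recipe"
58610764,"Menudo with corn masa, home recipe"
58617801,"Pozole-style soup with masa, home recipe"
58618654,"Corn masa porridge, home recipe"
58620443,"Flauta, corn tortilla, home recipe"
58641822,"Corn tortilla, plain, reduced fat"
58656249,"Corn tortilla, fried, reduced fat"
58756052,"Taco shell, corn, reduced fat"
58803958,"Tamale, plain, reduced fat"
58828800,"Tamale, with meat, reduced fat"
58883480,"Tamale, with chicken, reduced fat"
58908215,"Tostada shell, corn, reduced fat"
58922193,"Corn masa harina, reduced fat"
58929288,"Pupusa, cheese, reduced fat"
58962281,"Pupusa, bean, reduced fat"
58972514,"Gordita, corn masa, reduced fat"
58981070,"Sope, corn masa, reduced fat"
58981500,"Enchilada, cheese, corn tortilla, reduced fat"
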