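text,added,dairy,fruit_veg
"water, sugar (12%), cocoa (cocoa mass, cocoa butter), salt",2,,
"sugar",1,,
"milk, sugar, strawberry",2,1,3
"water, salt",,,
"sucralose",,,
"carbonated water, high fructose corn syrup, caramel colour",2 3,,
"organic cane sugar, almonds",1,,
"whole wheat flour, raisins, honey, skimmed milk powder",3,4,2
"apple juice concentrate, water",1,,1
"maltitol, sorbitol",,,
"oat milk (water, oats), sugar",2,,
"wheat flour; glucose-fructose syrup; palm oil",2,,
"tomatoes (60%), tomato paste, sugar, basil",3,,1 2
"milk chocolate (sugar, cocoa butter, milk powder), wheat flour",,1,
"water, fruit juice concentrate (apple, grape), citric acid",2,,2
"Sugar, Enriched Flour (Wheat Flour, Niacin), Corn Syrup",1 3,,
" honey ",1,,
"stevia extract, erythritol, natural flavours",,,
"yoghurt powder, dried strawberries",,1,2
"brown rice syrup, dates, cashews",1,,2
"skim milk, cream, lactose",,1 2 3,
"water, barley malt extract",2,,
"monk fruit extract, water",,,
"sweetened condensed milk, cocoa",1,1,
"carrot juice, orange juice concentrate",2,,1 2
"quinoa, amaranth, millet, buckwheat, chia, flax, sugar",,,
"flour, salt, yeast, water, oil, dextrose",6,,
"flour, salt, yeast, water, oil, spices, dextrose",,,
"maple syrup; molasses",1 2,,
"isomalt, acesulfame k, aspartame",,,
"agave nectar, banana puree",1,,2
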