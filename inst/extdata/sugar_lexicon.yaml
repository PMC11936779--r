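# Curated regular-expression lexicon for tagging sugar-related ingredients.
# Patterns are matched case-insensitively against a single parsed ingredient
# name. An ingredient matching any `exclusions` pattern is vetoed from all
# categories (non-caloric sweeteners and sugar alcohols carry no free sugars;
# plant-based "milks" carry no lactose). `added_sugar` follows the WHO free-
# sugar reading: fruit juices and fruit juice concentrates count as added.
# The list may be enriched whenever necessary; order is preserved.
added_sugar:
  - '\bsugars?\b'
  - '\bsyrups?\b'
  - '\bhoney\b'
  - '\bmolasses\b'
  - '\btreacle\b'
  - '\bsucrose\b'
  - '\bdextrose\b'
  - '\bglucose\b'
  - '\bfructose\b'
  - '\bmaltose\b'
  - '\bisoglucose\b'
  - '\btrehalose\b'
  - '\bmaltodextrins?\b'
  - '\bcorn sweeteners?\b'
  - '\bhigh[- ]fructose corn syrup\b'
  - '\bhfcs\b'
  - '\bagave( nectar)?\b'
  - '\bmaple( syrup)?\b'
  - '\bcaramel\b'
  - '\b(fruit )?juice concentrates?\b'
  - '\bconcentrated (fruit |apple |grape |pear )?juices?\b'
  - '\b(fruit|apple|grape|pear|orange|pineapple|white grape) juice\b'
  - '\bevaporated cane juice\b'
  - '\bcane juice\b'
  - '\bcane sugar\b'
  - '\bpanela\b'
  - '\bjaggery\b'
  - '\bmuscovado\b'
  - '\bdemerara\b'
  - '\bturbinado\b'
  - '\brapadura\b'
  - '\bpiloncillo\b'
  - '\binvert(ed)? (sugar|syrup)\b'
  - '\bgolden syrup\b'
  - '\b(brown )?rice syrup\b'
  - '\bbarley malt\b'
  - '\bmalt extract\b'
  - '\bmalt syrup\b'
  - '\bmalted barley (extract|syrup)\b'
  - '\bicing sugar\b'
  - '\bpowdered sugar\b'
  - '\bconfectioner.?s sugar\b'
  - '\bglucose[- ]fructose\b'
  - '\bfructose[- ]glucose\b'
  - '\bdate (syrup|paste|nectar)\b'
  - '\bcoconut (sugar|nectar|blossom)\b'
  - '\bhoney powder\b'
  - '\bsweetened condensed milk\b'
  - '\bcorn syrup solids\b'
  - '\brefiner.?s syrup\b'
  - '\bsorghum (syrup|molasses)\b'
  - '\btapioca syrup\b'
  - '\bfruit sugar\b'
  - '\bgalactose\b'
  - '\bglucose solids\b'
  - '\bdried (cane|glucose) syrup\b'
  - '\bnectars?\b'
  - '\bdextrins?\b'
dairy:
  - '\bmilk\b'
  - '\bbuttermilk\b'
  - '\bwhey\b'
  - '\blactose\b'
  - '\bcream\b'
  - '\byog(h)?urt\b'
  - '\bkefir\b'
  - '\bquark\b'
  - '\bskyr\b'
  - '\bcurd\b'
  - '\bfromage frais\b'
  - '\bmilk solids\b'
  - '\bmilk powder\b'
  - '\bdairy\b'
  - '\blactoserum\b'
fruit_veg:
  - '\bfruits?\b'
  - '\bapples?\b'
  - '\bapricots?\b'
  - '\bbananas?\b'
  - '\bberr(y|ies)\b'
  - '\bblueberr(y|ies)\b'
  - '\bstrawberr(y|ies)\b'
  - '\braspberr(y|ies)\b'
  - '\bblackberr(y|ies)\b'
  - '\bcherr(y|ies)\b'
  - '\bcranberr(y|ies)\b'
  - '\bgrapes?\b'
  - '\braisins?\b'
  - '\bsultanas?\b'
  - '\bdates?\b'
  - '\bfigs?\b'
  - '\bmango(es)?\b'
  - '\boranges?\b'
  - '\blemons?\b'
  - '\blimes?\b'
  - '\bpeach(es)?\b'
  - '\bpears?\b'
  - '\bpineapples?\b'
  - '\bplums?\b'
  - '\bprunes?\b'
  - '\bmelons?\b'
  - '\bwatermelons?\b'
  - '\bkiwis?\b'
  - '\bpapayas?\b'
  - '\bpassion ?fruit\b'
  - '\bpomegranates?\b'
  - '\bcurrants?\b'
  - '\bguavas?\b'
  - '\blychees?\b'
  - '\btomato(es)?\b'
  - '\bcarrots?\b'
  - '\bbeet(root)?s?\b'
  - '\bsweet potato(es)?\b'
  - '\bpumpkins?\b'
  - '\bsweetcorn\b'
  - '\bonions?\b'
  - '\bcoconuts?\b'
exclusions:
  - '\bsucralose\b'
  - '\baspartame\b'
  - '\bacesulfame\b'
  - '\bsaccharin\b'
  - '\bstevi(a|ol)\b'
  - '\bcyclamates?\b'
  - '\bneotame\b'
  - '\badvantame\b'
  - '\bmonk ?fruit\b'
  - '\bluo han guo\b'
  - '\bmaltitol\b'
  - '\bsorbitol\b'
  - '\bxylitol\b'
  - '\berythritol\b'
  - '\bisomalt\b'
  - '\bmannitol\b'
  - '\blactitol\b'
  - '\bpolydextrose\b'
  - '\b(almond|soy|soya|coconut|oat|rice|cashew|hemp|pea) (milk|drink)\b'
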