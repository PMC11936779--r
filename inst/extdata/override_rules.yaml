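# Categories and sub-categories for which total sugars is taken as the
# free-sugar value (their sugars are free sugars essentially by definition).
categories:
  - Juice Drinks
  - Carbonated Soft Drinks
  - Sweeteners & Sugar
  - Sugar & Gum Confectionery
subcategories:
  - Flavoured Water
  - Honey
  - Syrups
  - Ready To Drink (Iced) Tea
  - Water Based Ice Lollies, Pops & Sorbets
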