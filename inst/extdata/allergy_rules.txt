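# Representative allergy risk rules, one per line:
# comma-separated atoms, ?-prefixed variables, "->" between body and head.
# The four risk families are lactose, gluten, egg and fish.
Consumer(?c), Has_Allergy(?c, Lactose_Allergy), Has_Ean_No(?c, ?p), Has_Product_Additives_Name(?p, Aluminium_Silicate) -> HAS_LACTOSE_RISK(?c, Aluminium_Silicate)
Consumer(?c), Has_Allergy(?c, Lactose_Allergy), Has_Ean_No(?c, ?p), Has_Product_Additives_Name(?p, Lactitol) -> HAS_LACTOSE_RISK(?c, Lactitol)
Consumer(?c), Has_Allergy(?c, Gluten_Allergy), Has_Ean_No(?c, ?p), Has_Product_Additives_Name(?p, Wheat_Flour) -> HAS_GLUTEN_RISK(?c, Wheat_Flour)
Consumer(?c), Has_Allergy(?c, Gluten_Allergy), Has_Ean_No(?c, ?p), Has_Product_Additives_Name(?p, Glutamic_Acid) -> HAS_GLUTEN_RISK(?c, Glutamic_Acid)
Consumer(?c), Has_Allergy(?c, Egg_Allergy), Has_Ean_No(?c, ?p), Has_Product_Additives_Name(?p, Albumen) -> HAS_EGG_RISK(?c, Albumen)
Consumer(?c), Has_Allergy(?c, Egg_Allergy), Has_Ean_No(?c, ?p), Has_Product_Additives_Name(?p, Lysozyme) -> HAS_EGG_RISK(?c, Lysozyme)
Consumer(?c), Has_Allergy(?c, Fish_Allergy), Has_Ean_No(?c, ?p), Has_Product_Additives_Name(?p, Fish_Gelatine) -> HAS_FISH_RISK(?c, Fish_Gelatine)
Consumer(?c), Has_Allergy(?c, Fish_Allergy), Has_Ean_No(?c, ?p), Has_Product_Additives_Name(?p, Isinglass) -> HAS_FISH_RISK(?c, Isinglass)
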