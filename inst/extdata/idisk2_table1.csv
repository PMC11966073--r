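section,label,count
concept,Dietary supplement ingredient,8091
concept,Dietary supplement product,163806
concept,Drug,625
concept,Disease,786
concept,Therapeutic class,567
concept,System organ class,17
concept,Sign/symptoms,425
concept_total,Total,174317
relationship,is_effective_for,5245
relationship,has_therapeutic_class,4435
relationship,has_adverse_effect_on,2598
relationship,has_adverse_reaction,1342
relationship,has_ingredient,317062
relationship,interacts_with,3583
relationship_total,Total,334265
attribute,Company name,163806
attribute,Company address,163806
attribute,Product purpose,65097
attribute,Product risk,63623
attribute,Background,1289
attribute,Safety,1179
attribute,Mechanism of action,277
attribute,Source material,4277
attribute,Interaction rating,3086
attribute,Effectiveness rating,4623
attribute_total,Total,471063
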