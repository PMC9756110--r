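task,met
rest,1.3
cooking,2
washing_clothes,3.5
walking,3.3
water_collection,5
gardening,4
rice_planting,4.5
harvesting,4
firewood_collection,4.8
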