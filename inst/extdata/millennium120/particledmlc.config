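# MLC physical configuration
model_name = Millennium120
density = 17.6
tip_radius = 8
tip_angle = 11.3
tip_max_thickness = 6.7
leaf_offset = 0.01
z_upper = 50.9
physical_thickness = 6.7
sad = 100
inner_leaves = 40
inner_width = 0.5
outer_leaves = 20
outer_width = 1
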