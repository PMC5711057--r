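# MLC physical configuration
model_name = HD120
density = 18.9
tip_radius = 16
tip_angle = 0
tip_max_thickness = 6.9
leaf_offset = 0.01
z_upper = 50.9
physical_thickness = 6.9
sad = 100
inner_leaves = 32
inner_width = 0.25
outer_leaves = 28
outer_width = 0.5
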