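{"features":[{"name":"blood","label":"blood in the surgical field","group":"surgical_field","kind":"ordinal","levels":[0,1,2,3,4],"relevant_threshold":2},{"name":"smoke","label":"smoke in the surgical field","group":"surgical_field","kind":"ordinal","levels":[0,1,2,3],"relevant_threshold":1},{"name":"azygos_vein","label":"azygos vein","group":"anatomy","kind":"binary","levels":[0,1],"relevant_threshold":null},{"name":"gastric_tube","label":"gastric tube","group":"anatomy","kind":"binary","levels":[0,1],"relevant_threshold":null},{"name":"vessel_sealer","label":"vessel sealer","group":"instrument","kind":"binary","levels":[0,1],"relevant_threshold":null},{"name":"cautery_hook","label":"permanent cautery hook","group":"instrument","kind":"binary","levels":[0,1],"relevant_threshold":null},{"name":"suction","label":"suction","group":"instrument","kind":"binary","levels":[0,1],"relevant_threshold":null},{"name":"scissors","label":"scissors","group":"instrument","kind":"binary","levels":[0,1],"relevant_threshold":null},{"name":"large_clip_applier","label":"large clip applier","group":"instrument","kind":"binary","levels":[0,1],"relevant_threshold":null},{"name":"metal_clip_applier","label":"metal clip applier","group":"instrument","kind":"binary","levels":[0,1],"relevant_threshold":null}]}
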