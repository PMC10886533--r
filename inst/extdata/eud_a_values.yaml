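# Organ-specific volume-effect exponents for the generalized EUD
# (13 organs at risk of the stage II seminoma planning cohort)
bladder: 2
large_bowel: 5
small_bowel: 5
spinal_cord: 20
kidneys: 1.5
liver: 0.8
pancreas: 5
rectum: 5
stomach: 7
femurs: 3
pelvic_ilium: 3
sacrum: 3
vertebral_bodies: 8
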