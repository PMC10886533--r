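# General-population (SEER) cancer incidence per 10,000 person-years
# for the eight organs with population baselines.
bladder: 1.8
large_bowel: 2.6
small_bowel: 0.25
kidneys: 1.7
liver: 0.9
pancreas: 1.3
rectum: 1.1
stomach: 0.7
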