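organ,modality,ear,lar
bladder,3D,2.4,0.34
large_bowel,3D,3.0,0.22
small_bowel,3D,2.6,0.19
spinal_cord,3D,8.2,1.15
kidneys,3D,3.5,0.26
liver,3D,1.17,0.13
pancreas,3D,1.84,0.14
rectum,3D,3.2,0.46
stomach,3D,3.2,0.49
bladder,VMAT,3.0,0.42
large_bowel,VMAT,1.8,0.13
small_bowel,VMAT,1.4,0.10
spinal_cord,VMAT,5.9,0.82
kidneys,VMAT,3.4,0.25
liver,VMAT,1.70,0.19
pancreas,VMAT,1.17,0.09
rectum,VMAT,4.7,0.67
stomach,VMAT,3.6,0.55
bladder,PBS,0.86,0.12
large_bowel,PBS,0.41,0.03
small_bowel,PBS,0.59,0.04
spinal_cord,PBS,6.1,0.85
kidneys,PBS,0.81,0.06
liver,PBS,0.10,0.012
pancreas,PBS,1.14,0.08
rectum,PBS,2.0,0.28
stomach,PBS,0.32,0.05
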