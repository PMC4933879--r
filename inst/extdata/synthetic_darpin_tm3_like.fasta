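>synthetic_darpin_tm3_like | SYNTHETIC 169-residue DARPin-like construct (His-tagged N3C scaffold layout); NOT a deposited or published sequence. Designed so that limited-proteolysis fragment arithmetic is exactly reproducible: residue 149 is Ala (71.08 Da step between fragments 1-149 and 1-148), fragment 1-149 has average mass ~15.8 kDa, and fragment 11-160 matches fragment 1-148 within 0.1 Da; no other contiguous fragment matches either mass within 2 Da.
MRGSHHHHHHGSDLGKKLLEAARAGQDDEVRILMANGADVNAKDFSGKTPLHLAAYDGHL
EIVEVLLKAGADVNAKDNRGETPLHLAAAVGHLEIVEVLLKYGADVNAKDARGRTPLRLA
ATNGHLEIVEVLLKNGADVNAQDKSGKTASATIIDHTSEQLAEILQKLN
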