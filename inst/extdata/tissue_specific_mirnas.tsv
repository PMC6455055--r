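tissue_class	mirna
Bud	miR1128-x
Bud	miR781-y
Bud	miR8590-y
Bud	miR870-y
Bud	miR9759-y
Leaf	miR1042-x
Leaf	miR1045-x
Leaf	miR1057-y
Leaf	miR1063-x
Leaf	miR1515-x
Leaf	miR164-y
Leaf	miR1866-y
Leaf	miR2083-y
Leaf	miR2111-y
Leaf	miR2275-y
Leaf	miR393-x
Leaf	miR5061-y
Leaf	miR5181-y
Leaf	miR5523-y
Leaf	miR5538-x
Leaf	miR5653-y
Leaf	miR6173-y
Leaf	miR6281-x
Leaf	miR7528-y
Leaf	miR7711-x
Leaf	miR7725-x
Leaf	miR845-z
Leaf	miR858-y
Leaf	miR8665-y
Leaf	miR9569-x
Leaf	novel-m0703-5p
Leaf	novel-m0722-5p
Leaf	novel-m0945-3p
Leaf	novel-m0953-5p
Leaf	novel-m1089-3p
Leaf	novel-m1125-5p
Stem	miR1127-x
Stem	miR1865-x
Stem	miR2275-x
Stem	miR3512-y
Stem	miR3630-x
Stem	miR4388-y
Stem	miR474-x
Stem	miR474-y
Stem	miR5021-x
Stem	miR5385-x
Stem	miR5834-x
Stem	miR6485-x
Stem	miR7713-x
Stem	miR7717-x
Stem	miR7762-y
Stem	miR8007-y
Stem	miR8681-y
Stem	miR9863-x
Stem	novel-m0024-3p
Stem	novel-m0095-3p
Stem	novel-m0155-3p
Stem	novel-m0331-5p
Stem	novel-m0392-5p
Stem	novel-m0828-3p
Stem	novel-m0906-3p
Stem	novel-m1037-3p
Stem	novel-m1040-3p
Stem	novel-m1041-5p
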