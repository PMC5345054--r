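taxonomy 2009 original description 2009
(Scelianoma Scelianoma_elydimorpha)

taxonomy 2012 cladistic revision 2012
(Scelianoma Scelianoma_elydimorpha)

taxonomy 2017 fossil treatment 2017
(Scelianoma Scelianoma_elydimorpha Scelianoma_compacta)

articulation 2009-2012 alignment
[2009.Scelianoma equals 2012.Scelianoma]
[2009.Scelianoma_elydimorpha equals 2012.Scelianoma_elydimorpha]

articulation 2012-2017 alignment
[2012.Scelianoma is_included_in 2017.Scelianoma]
[2012.Scelianoma_elydimorpha equals 2017.Scelianoma_elydimorpha]

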