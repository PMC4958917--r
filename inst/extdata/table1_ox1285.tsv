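# Clonotypes identified in the OX1285 breast tumor exome by three CDR3
# detection tools, with deep-repertoire (ImmunoSeq) abundances where the
# clone was present in the deep dataset (NA otherwise).
# Encoding: integer = reads supporting the clone; ">0" = present only as
# rescued out-of-frame evidence (count unknown). Under rescued_policy
# "count" a ">0" entry is a detection; under "ignore" it is not — the dual
# policy is required to reproduce both the per-tool overlap fractions and
# the two-or-more-tools clone count reported for this sample.
clone_id	clonotyper	imseq	mitcr	deep_abundance_pct
c1	1	>0	6	8.10
c2	0	0	1	1.67
c3	0	1	1	0.89
c4	0	2	2	0.71
c5	0	1	1	0.52
c6	0	2	2	0.24
c7	0	1	1	0.21
c8	0	1	1	0.13
c9	0	1	0	0.12
c10	0	1	1	0.06
c11	0	>0	1	0.04
c12	1	1	1	0.03
c13	3	>0	3	0.02
c14	0	>0	1	0.01
c15	0	0	1	0.003
c16	2	2	0	NA
c17	0	1	1	NA
c18	0	0	1	NA
c19	0	0	1	NA
c20	0	0	1	NA
c21	0	0	1	NA
c22	1	1	1	NA
c23	0	>0	2	NA
c24	0	0	2	NA
c25	2	2	2	NA
c26	0	0	3	NA
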