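SET_TOP	synthetic example set enriched at the head of a ranked list	gene_0001	gene_0002	gene_0003	gene_0005	gene_0008
SET_MIXED	synthetic example set scattered through the list	gene_0004	gene_0020	gene_0100	gene_0250	gene_0400	gene_0600
SET_BOTTOM	synthetic example set enriched at the tail	gene_0995	gene_0996	gene_0997	gene_0998	gene_0999
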