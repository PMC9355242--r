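# In vivo disulfide-crosslinking outcomes for engineered FhaC Cys pairs
# (dsbA-null background). EXPERIMENTAL INPUT DATA for interpretation reports,
# not computed output. Periplasmic sites: 48 (H1-POTRA1 linker), 86 (POTRA1),
# 167/176/187/195 (POTRA2). Surface sites: 224 (L1), 290 (L3), 342 (L4),
# 391 (L5), 503 (L7), 545 (L8). crosslink: yes / weak / no.
periplasmic_site,surface_site,crosslink
195,224,yes
176,224,yes
48,224,yes
48,545,yes
167,224,weak
187,224,no
86,224,no
195,290,no
195,342,no
195,391,no
195,503,no
195,545,no
176,290,no
176,342,no
176,391,no
176,503,no
176,545,no
187,290,no
187,342,no
187,391,no
187,503,no
187,545,no
167,290,no
167,342,no
167,391,no
167,503,no
167,545,no
48,290,no
48,342,no
48,391,no
48,503,no
86,290,no
86,342,no
86,391,no
86,503,no
86,545,no
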