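gene	members
MT-TM	10;25;45
MT-TM	9;12;23
MT-TM	13;22;46
MT-TF	10;25;45
MT-TF	9;12;23
MT-TF	13;22;46
MT-TF	18;55
MT-TF	19;56
MT-TV	10;25;45
MT-TV	9;12;23
MT-TV	13;22;46
MT-TL1	10;25;45
MT-TL1	9;12;23
MT-TL1	13;22;46
MT-TL1	18;55
MT-TL1	19;56
MT-TI	10;25;45
MT-TI	9;12;23
MT-TI	13;22;46
MT-TQ	10;25;45
MT-TQ	9;12;23
MT-TQ	13;22;46
MT-TQ	18;55
MT-TQ	19;56
MT-TW	10;25;45
MT-TW	9;12;23
MT-TW	13;22;46
MT-TA	10;25;45
MT-TA	9;12;23
MT-TA	13;22;46
MT-TN	10;25;45
MT-TN	9;12;23
MT-TN	13;22;46
MT-TC	10;25;45
MT-TC	9;12;23
MT-TC	13;22;46
MT-TY	10;25;45
MT-TY	9;12;23
MT-TY	13;22;46
MT-TS1	10;25;45
MT-TS1	9;12;23
MT-TS1	13;22;46
MT-TD	10;25;45
MT-TD	9;12;23
MT-TD	13;22;46
MT-TK	10;25;45
MT-TK	9;12;23
MT-TK	13;22;46
MT-TG	10;25;45
MT-TG	9;12;23
MT-TG	13;22;46
MT-TR	10;25;45
MT-TR	9;12;23
MT-TR	13;22;46
MT-TH	10;25;45
MT-TH	9;12;23
MT-TH	13;22;46
MT-TL2	10;25;45
MT-TL2	9;12;23
MT-TL2	13;22;46
MT-TL2	18;55
MT-TL2	19;56
MT-TE	10;25;45
MT-TE	9;12;23
MT-TE	13;22;46
MT-TE	18;55
MT-TE	19;56
MT-TT	10;25;45
MT-TT	9;12;23
MT-TT	13;22;46
MT-TP	10;25;45
MT-TP	9;12;23
MT-TP	13;22;46
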