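analyte_id	metabolite_class	lloq	uloq
C0	free_carnitine	1	200
C2	acylcarnitine	0.01	25
C3	acylcarnitine	0.01	25
C3:1	acylcarnitine	0.01	25
C3-OH	acylcarnitine	0.01	25
C4	acylcarnitine	0.01	25
C4:1	acylcarnitine	0.01	25
C4-OH	acylcarnitine	0.01	25
C5	acylcarnitine	0.01	25
C5:1	acylcarnitine	0.01	25
C5:1-DC	acylcarnitine	0.01	25
C5-DC	acylcarnitine	0.01	25
C5-M-DC	acylcarnitine	0.01	25
C5-OH	acylcarnitine	0.01	25
C6	acylcarnitine	0.01	25
C6:1	acylcarnitine	0.01	25
C7-DC	acylcarnitine	0.01	25
C8	acylcarnitine	0.01	25
C9	acylcarnitine	0.01	25
C10	acylcarnitine	0.01	25
C10:1	acylcarnitine	0.01	25
C10:2	acylcarnitine	0.01	25
C12	acylcarnitine	0.01	25
C12:1	acylcarnitine	0.01	25
C12-DC	acylcarnitine	0.01	25
C14	acylcarnitine	0.01	25
C14:1	acylcarnitine	0.01	25
C14:1-OH	acylcarnitine	0.01	25
C14:2	acylcarnitine	0.01	25
C14:2-OH	acylcarnitine	0.01	25
C16	acylcarnitine	0.01	25
C16:1	acylcarnitine	0.01	25
C16:1-OH	acylcarnitine	0.01	25
C16:2	acylcarnitine	0.01	25
C16:2-OH	acylcarnitine	0.01	25
C16-OH	acylcarnitine	0.01	25
C18	acylcarnitine	0.01	25
C18:1	acylcarnitine	0.01	25
C18:1-OH	acylcarnitine	0.01	25
C18:2	acylcarnitine	0.01	25
H1	hexose	100	20000
Ala	amino_acid	1	1000
Arg	amino_acid	1	1000
Asn	amino_acid	1	1000
Asp	amino_acid	1	1000
Cit	amino_acid	1	1000
Gln	amino_acid	1	1000
Glu	amino_acid	1	1000
Gly	amino_acid	1	1000
His	amino_acid	1	1000
Ile	amino_acid	1	1000
Leu	amino_acid	1	1000
Lys	amino_acid	1	1000
Met	amino_acid	1	1000
Orn	amino_acid	1	1000
Phe	amino_acid	1	1000
Pro	amino_acid	1	1000
Ser	amino_acid	1	1000
Thr	amino_acid	1	1000
Trp	amino_acid	1	1000
Tyr	amino_acid	1	1000
Val	amino_acid	1	1000
Ac-Orn	biogenic_amine	0.05	100
ADMA	biogenic_amine	0.05	100
alpha-AAA	biogenic_amine	0.05	100
Carnosine	biogenic_amine	0.05	100
Creatinine	biogenic_amine	0.05	100
DOPA	biogenic_amine	0.05	100
Dopamine	biogenic_amine	0.05	100
Histamine	biogenic_amine	0.05	100
Kynurenine	biogenic_amine	0.05	100
Met-SO	biogenic_amine	0.05	100
Nitro-Tyr	biogenic_amine	0.05	100
PEA	biogenic_amine	0.05	100
Putrescine	biogenic_amine	0.05	100
Sarcosine	biogenic_amine	0.05	100
SDMA	biogenic_amine	0.05	100
Serotonin	biogenic_amine	0.05	100
Spermidine	biogenic_amine	0.05	100
Spermine	biogenic_amine	0.05	100
t4-OH-Pro	biogenic_amine	0.05	100
Taurine	biogenic_amine	0.05	100
total-DMA	biogenic_amine	0.05	100
lysoPC a C14:0	lysoPC	0.05	400
lysoPC a C16:0	lysoPC	0.05	400
lysoPC a C16:1	lysoPC	0.05	400
lysoPC a C17:0	lysoPC	0.05	400
lysoPC a C18:0	lysoPC	0.05	400
lysoPC a C18:1	lysoPC	0.05	400
lysoPC a C18:2	lysoPC	0.05	400
lysoPC a C20:3	lysoPC	0.05	400
lysoPC a C20:4	lysoPC	0.05	400
lysoPC a C24:0	lysoPC	0.05	400
lysoPC a C26:0	lysoPC	0.05	400
lysoPC a C26:1	lysoPC	0.05	400
lysoPC a C28:0	lysoPC	0.05	400
lysoPC a C28:1	lysoPC	0.05	400
PC aa C24:0	PC_aa	0.05	1500
PC aa C26:0	PC_aa	0.05	1500
PC aa C28:1	PC_aa	0.05	1500
PC aa C30:0	PC_aa	0.05	1500
PC aa C30:2	PC_aa	0.05	1500
PC aa C32:0	PC_aa	0.05	1500
PC aa C32:1	PC_aa	0.05	1500
PC aa C32:2	PC_aa	0.05	1500
PC aa C32:3	PC_aa	0.05	1500
PC aa C34:1	PC_aa	0.05	1500
PC aa C34:2	PC_aa	0.05	1500
PC aa C34:3	PC_aa	0.05	1500
PC aa C34:4	PC_aa	0.05	1500
PC aa C36:0	PC_aa	0.05	1500
PC aa C36:1	PC_aa	0.05	1500
PC aa C36:2	PC_aa	0.05	1500
PC aa C36:3	PC_aa	0.05	1500
PC aa C36:4	PC_aa	0.05	1500
PC aa C36:5	PC_aa	0.05	1500
PC aa C36:6	PC_aa	0.05	1500
PC aa C38:0	PC_aa	0.05	1500
PC aa C38:1	PC_aa	0.05	1500
PC aa C38:3	PC_aa	0.05	1500
PC aa C38:4	PC_aa	0.05	1500
PC aa C38:5	PC_aa	0.05	1500
PC aa C38:6	PC_aa	0.05	1500
PC aa C40:1	PC_aa	0.05	1500
PC aa C40:2	PC_aa	0.05	1500
PC aa C40:3	PC_aa	0.05	1500
PC aa C40:4	PC_aa	0.05	1500
PC aa C40:5	PC_aa	0.05	1500
PC aa C40:6	PC_aa	0.05	1500
PC aa C42:0	PC_aa	0.05	1500
PC aa C42:1	PC_aa	0.05	1500
PC aa C42:2	PC_aa	0.05	1500
PC aa C42:4	PC_aa	0.05	1500
PC aa C42:5	PC_aa	0.05	1500
PC aa C42:6	PC_aa	0.05	1500
PC ae C30:0	PC_ae	0.05	400
PC ae C30:1	PC_ae	0.05	400
PC ae C30:2	PC_ae	0.05	400
PC ae C32:1	PC_ae	0.05	400
PC ae C32:2	PC_ae	0.05	400
PC ae C34:0	PC_ae	0.05	400
PC ae C34:1	PC_ae	0.05	400
PC ae C34:2	PC_ae	0.05	400
PC ae C34:3	PC_ae	0.05	400
PC ae C36:0	PC_ae	0.05	400
PC ae C36:1	PC_ae	0.05	400
PC ae C36:2	PC_ae	0.05	400
PC ae C36:3	PC_ae	0.05	400
PC ae C36:4	PC_ae	0.05	400
PC ae C36:5	PC_ae	0.05	400
PC ae C38:0	PC_ae	0.05	400
PC ae C38:1	PC_ae	0.05	400
PC ae C38:2	PC_ae	0.05	400
PC ae C38:3	PC_ae	0.05	400
PC ae C38:4	PC_ae	0.05	400
PC ae C38:5	PC_ae	0.05	400
PC ae C38:6	PC_ae	0.05	400
PC ae C40:1	PC_ae	0.05	400
PC ae C40:2	PC_ae	0.05	400
PC ae C40:3	PC_ae	0.05	400
PC ae C40:4	PC_ae	0.05	400
PC ae C40:5	PC_ae	0.05	400
PC ae C40:6	PC_ae	0.05	400
PC ae C42:0	PC_ae	0.05	400
PC ae C42:1	PC_ae	0.05	400
PC ae C42:2	PC_ae	0.05	400
PC ae C42:3	PC_ae	0.05	400
PC ae C42:4	PC_ae	0.05	400
PC ae C42:5	PC_ae	0.05	400
PC ae C44:3	PC_ae	0.05	400
PC ae C44:4	PC_ae	0.05	400
PC ae C44:5	PC_ae	0.05	400
PC ae C44:6	PC_ae	0.05	400
SM (OH) C14:1	SM	0.05	600
SM (OH) C16:1	SM	0.05	600
SM (OH) C22:1	SM	0.05	600
SM (OH) C22:2	SM	0.05	600
SM (OH) C24:1	SM	0.05	600
SM C16:0	SM	0.05	600
SM C16:1	SM	0.05	600
SM C18:0	SM	0.05	600
SM C18:1	SM	0.05	600
SM C20:2	SM	0.05	600
SM C22:3	SM	0.05	600
SM C24:0	SM	0.05	600
SM C24:1	SM	0.05	600
SM C26:0	SM	0.05	600
SM C26:1	SM	0.05	600
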