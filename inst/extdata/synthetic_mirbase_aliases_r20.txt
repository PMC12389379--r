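MI0001000	hsa-mir-21
MIMAT0001000	hsa-miR-21
MI0001001	hsa-mir-34a
MIMAT0001001	hsa-miR-34a
MI0001002	hsa-mir-195
MIMAT0001002	hsa-miR-195
MI0001003	hsa-mir-181a
MIMAT0001003	hsa-miR-181a
MI0001004	hsa-mir-200c
MIMAT0001004	hsa-miR-200c
MI0001005	hsa-mir-934
MIMAT0001005	hsa-miR-934
MI0001006	hsa-mir-342
MIMAT0001006	hsa-miR-342
MI0001007	hsa-mir-138
MIMAT0001007	hsa-miR-138
MI0001008	hsa-mir-196a
MIMAT0001008	hsa-miR-196a
MI0001009	hsa-mir-129
MIMAT0001009	hsa-miR-129
MI0001100	hsa-mir-133b
MIMAT0001100	hsa-miR-133b;hsa-miR-133b-5p
MIMAT0006100	hsa-miR-133b-3p
MI0001101	hsa-mir-19a
MIMAT0001101	hsa-miR-19a;hsa-miR-19a-5p
MIMAT0006101	hsa-miR-19a-3p
MI0001102	hsa-mir-27a
MIMAT0001102	hsa-miR-27a;hsa-miR-27a-5p
MIMAT0006102	hsa-miR-27a-3p
MI0001103	hsa-mir-29b
MIMAT0001103	hsa-miR-29b;hsa-miR-29b-5p
MIMAT0006103	hsa-miR-29b-3p
MI0001104	hsa-mir-135b
MIMAT0001104	hsa-miR-135b;hsa-miR-135b-5p
MIMAT0006104	hsa-miR-135b-3p
MI0001105	hsa-mir-203
MIMAT0001105	hsa-miR-203;hsa-miR-203-5p
MIMAT0006105	hsa-miR-203-3p
MI0001106	hsa-mir-148a
MIMAT0001106	hsa-miR-148a;hsa-miR-148a-5p
MIMAT0006106	hsa-miR-148a-3p
MI0001107	hsa-mir-363
MIMAT0001107	hsa-miR-363;hsa-miR-363-5p
MIMAT0006107	hsa-miR-363-3p
MI0001108	hsa-mir-519d
MIMAT0001108	hsa-miR-519d;hsa-miR-519d-5p
MIMAT0006108	hsa-miR-519d-3p
MI0001109	hsa-mir-338
MIMAT0001109	hsa-miR-338;hsa-miR-338-5p
MIMAT0006109	hsa-miR-338-3p
MI0001110	hsa-mir-17
MIMAT0001110	hsa-miR-17;hsa-miR-17-5p
MIMAT0006110	hsa-miR-17-3p
MI0001111	hsa-mir-155
MIMAT0001111	hsa-miR-155;hsa-miR-155-5p
MIMAT0006111	hsa-miR-155-3p
MI0001112	hsa-mir-143
MIMAT0001112	hsa-miR-143;hsa-miR-143-5p
MIMAT0006112	hsa-miR-143-3p
MI0001113	hsa-mir-145
MIMAT0001113	hsa-miR-145;hsa-miR-145-5p
MIMAT0006113	hsa-miR-145-3p
MI0001114	hsa-mir-106a
MIMAT0001114	hsa-miR-106a;hsa-miR-106a-5p
MIMAT0006114	hsa-miR-106a-3p
MI0001115	hsa-mir-221
MIMAT0001115	hsa-miR-221;hsa-miR-221-5p
MIMAT0006115	hsa-miR-221-3p
MI0001116	hsa-mir-222
MIMAT0001116	hsa-miR-222;hsa-miR-222-5p
MIMAT0006116	hsa-miR-222-3p
MI0001117	hsa-mir-31
MIMAT0001117	hsa-miR-31;hsa-miR-31-5p
MIMAT0006117	hsa-miR-31-3p
MI0001118	hsa-mir-92a
MIMAT0001118	hsa-miR-92a;hsa-miR-92a-5p
MIMAT0006118	hsa-miR-92a-3p
MI0001119	hsa-mir-1
MIMAT0001119	hsa-miR-1;hsa-miR-1-5p
MIMAT0006119	hsa-miR-1-3p
MI0000060	hsa-let-7a-1;hsa-let-7a
MIMAT0000062	hsa-let-7a;hsa-let-7a-5p
MIMAT0004481	hsa-let-7a-3p
MI0000063	hsa-let-7b
MIMAT0000063	hsa-let-7b;hsa-let-7b-5p
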