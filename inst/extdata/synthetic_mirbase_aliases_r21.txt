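MI0001000	hsa-mir-21
MIMAT0001000	hsa-miR-21;hsa-miR-21-5p
MIMAT0006000	hsa-miR-21-3p
MI0001001	hsa-mir-34a
MIMAT0001001	hsa-miR-34a;hsa-miR-34a-5p
MIMAT0006001	hsa-miR-34a-3p
MI0001002	hsa-mir-195
MIMAT0001002	hsa-miR-195;hsa-miR-195-5p
MIMAT0006002	hsa-miR-195-3p
MI0001003	hsa-mir-181a
MIMAT0001003	hsa-miR-181a;hsa-miR-181a-5p
MIMAT0006003	hsa-miR-181a-3p
MI0001004	hsa-mir-200c
MIMAT0001004	hsa-miR-200c;hsa-miR-200c-5p
MIMAT0006004	hsa-miR-200c-3p
MI0001005	hsa-mir-934
MIMAT0001005	hsa-miR-934;hsa-miR-934-5p
MIMAT0006005	hsa-miR-934-3p
MI0001006	hsa-mir-342
MIMAT0001006	hsa-miR-342;hsa-miR-342-5p
MIMAT0006006	hsa-miR-342-3p
MI0001007	hsa-mir-138
MIMAT0001007	hsa-miR-138;hsa-miR-138-5p
MIMAT0006007	hsa-miR-138-3p
MI0001008	hsa-mir-196a
MIMAT0001008	hsa-miR-196a;hsa-miR-196a-5p
MIMAT0006008	hsa-miR-196a-3p
MI0001009	hsa-mir-129
MIMAT0001009	hsa-miR-129;hsa-miR-129-5p
MIMAT0006009	hsa-miR-129-3p
MI0001010	hsa-mir-133b
MIMAT0001010	hsa-miR-133b;hsa-miR-133b-5p
MIMAT0006010	hsa-miR-133b-3p
MI0001011	hsa-mir-19a
MIMAT0001011	hsa-miR-19a;hsa-miR-19a-5p
MIMAT0006011	hsa-miR-19a-3p
MI0001012	hsa-mir-27a
MIMAT0001012	hsa-miR-27a;hsa-miR-27a-5p
MIMAT0006012	hsa-miR-27a-3p
MI0001013	hsa-mir-29b
MIMAT0001013	hsa-miR-29b;hsa-miR-29b-5p
MIMAT0006013	hsa-miR-29b-3p
MI0001014	hsa-mir-135b
MIMAT0001014	hsa-miR-135b;hsa-miR-135b-5p
MIMAT0006014	hsa-miR-135b-3p
MI0001015	hsa-mir-203
MIMAT0001015	hsa-miR-203;hsa-miR-203-5p
MIMAT0006015	hsa-miR-203-3p
MI0001016	hsa-mir-148a
MIMAT0001016	hsa-miR-148a;hsa-miR-148a-5p
MIMAT0006016	hsa-miR-148a-3p
MI0001017	hsa-mir-363
MIMAT0001017	hsa-miR-363;hsa-miR-363-5p
MIMAT0006017	hsa-miR-363-3p
MI0001018	hsa-mir-519d
MIMAT0001018	hsa-miR-519d;hsa-miR-519d-5p
MIMAT0006018	hsa-miR-519d-3p
MI0001019	hsa-mir-338
MIMAT0001019	hsa-miR-338;hsa-miR-338-5p
MIMAT0006019	hsa-miR-338-3p
MI0001020	hsa-mir-17
MIMAT0001020	hsa-miR-17;hsa-miR-17-5p
MIMAT0006020	hsa-miR-17-3p
MI0001021	hsa-mir-155
MIMAT0001021	hsa-miR-155;hsa-miR-155-5p
MIMAT0006021	hsa-miR-155-3p
MI0001022	hsa-mir-143
MIMAT0001022	hsa-miR-143;hsa-miR-143-5p
MIMAT0006022	hsa-miR-143-3p
MI0001023	hsa-mir-145
MIMAT0001023	hsa-miR-145;hsa-miR-145-5p
MIMAT0006023	hsa-miR-145-3p
MI0001024	hsa-mir-106a
MIMAT0001024	hsa-miR-106a;hsa-miR-106a-5p
MIMAT0006024	hsa-miR-106a-3p
MI0001025	hsa-mir-221
MIMAT0001025	hsa-miR-221;hsa-miR-221-5p
MIMAT0006025	hsa-miR-221-3p
MI0001026	hsa-mir-222
MIMAT0001026	hsa-miR-222;hsa-miR-222-5p
MIMAT0006026	hsa-miR-222-3p
MI0001027	hsa-mir-31
MIMAT0001027	hsa-miR-31;hsa-miR-31-5p
MIMAT0006027	hsa-miR-31-3p
MI0001028	hsa-mir-92a
MIMAT0001028	hsa-miR-92a;hsa-miR-92a-5p
MIMAT0006028	hsa-miR-92a-3p
MI0001029	hsa-mir-1
MIMAT0001029	hsa-miR-1;hsa-miR-1-5p
MIMAT0006029	hsa-miR-1-3p
MI0000060	hsa-let-7a-1;hsa-let-7a
MIMAT0000062	hsa-let-7a;hsa-let-7a-5p
MIMAT0004481	hsa-let-7a-3p
MI0000063	hsa-let-7b
MIMAT0000063	hsa-let-7b;hsa-let-7b-5p
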