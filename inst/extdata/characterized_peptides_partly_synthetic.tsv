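name	precursor	leader	core	cut_rule	fully_modified_n	synthetic
nisin_A	MSTKDFNLDLVSVSKKDSGASPRITSISLCTPGCKTGALMGCNMKTATCHCSIHVSK	MSTKDFNLDLVSVSKKDSGASPR	ITSISLCTPGCKTGALMGCNMKTATCHCSIHVSK	GASPR	8	FALSE
nisin_Z	MSTKDFNLDLVSVSKKDSGASPRITSISLCTPGCKTGALMGCNMKTATCNCSIHVSK	MSTKDFNLDLVSVSKKDSGASPR	ITSISLCTPGCKTGALMGCNMKTATCNCSIHVSK	GASPR	8	FALSE
subtilin	MSKFDDFDLDVVKVSKQDSKITPQWKSESLCTPGCVTGALQTCFLQTLTCNCKISK	MSKFDDFDLDVVKVSKQDSKITPQ	WKSESLCTPGCVTGALQTCFLQTLTCNCKISK	PQ	NA	FALSE
synthetic_variant_01	MSKFDDFDLDVVKVSKQDSKITPQWSSESLCTPGCVTGAVVTCFEPTLTCNCKISK	MSKFDDFDLDVVKVSKQDSKITPQ	WSSESLCTPGCVTGAVVTCFEPTLTCNCKISK	PQ	NA	TRUE
synthetic_variant_02	MNNEDFNLDLIKISKENNSGASPKYVSISNCTPGCETGALMYCNMKTKTCHCPGTVSK	MNNEDFNLDLIKISKENNSGASPK	YVSISNCTPGCETGALMYCNMKTKTCHCPGTVSK	PK	NA	TRUE
synthetic_variant_03	MSTKDFNLDLVSVSKKDSGASPRWKSESLCTPYCVTQALQTCFLQTLTCNCKISK	MSTKDFNLDLVSVSKKDSGASPR	WKSESLCTPYCVTQALQTCFLQTLTCNCKISK	GASPR	NA	TRUE
synthetic_variant_04	MSKFDDFDLDVVKVSKQDSKITPQITSISRCTPGCKTGALMGCNMKTATCHCSVHVSK	MSKFDDFDLDVVKVSKQDSKITPQ	ITSISRCTPGCKTGALMGCNMKTATCHCSVHVSK	PQ	NA	TRUE
synthetic_variant_05	MNNEDFNLDLIKISKENNSGASPKWFSSSLCTPGCVTGELCTCFLETATCNCKISE	MNNEDFNLDLIKISKENNSGASPK	WFSSSLCTPGCVTGELCTCFLETATCNCKISE	PK	NA	TRUE
synthetic_variant_06	MSTKDFNLDLVSVSKKDSGASPRITSISMCTPNCKTLANMCCNSSTATCHCSIHVSK	MSTKDFNLDLVSVSKKDSGASPR	ITSISMCTPNCKTLANMCCNSSTATCHCSIHVSK	GASPR	NA	TRUE
synthetic_variant_07	MSKFDDFDLDVVKVSKQDSKITPQWCSESLCTPGCDTGPLQTCFLPTLTCVCKIRK	MSKFDDFDLDVVKVSKQDSKITPQ	WCSESLCTPGCDTGPLQTCFLPTLTCVCKIRK	PQ	NA	TRUE
synthetic_variant_08	MNNEDFNLDLIKISKENNSGASPKYTSISLCTPGCKTGALMGCNMKTATCHCDIASSK	MNNEDFNLDLIKISKENNSGASPK	YTSISLCTPGCKTGALMGCNMKTATCHCDIASSK	PK	NA	TRUE
synthetic_variant_09	MSTKDFNLDLVSVSKKDSGASPRWKSISLCTPLCVTGALQRCFSKTLTCNCKIGK	MSTKDFNLDLVSVSKKDSGASPR	WKSISLCTPLCVTGALQRCFSKTLTCNCKIGK	GASPR	NA	TRUE
synthetic_variant_10	MSKFDDFDLDVVKVSKQDSKITPQIQSISLCTPICKTGALMICNMKTATCHCSPWVSK	MSKFDDFDLDVVKVSKQDSKITPQ	IQSISLCTPICKTGALMICNMKTATCHCSPWVSK	PQ	NA	TRUE
synthetic_variant_11	MNNEDFNLDLIKISKENNSGASPKWKSVSLCTMGCPTGALQTCKLFTGTCECKISK	MNNEDFNLDLIKISKENNSGASPK	WKSVSLCTMGCPTGALQTCKLFTGTCECKISK	PK	NA	TRUE
synthetic_variant_12	MSTKDFNLDLVSVSKKDSGASPRITSMSLCTPGCKTGFLMGCMPKTHTCHCSILVSK	MSTKDFNLDLVSVSKKDSGASPR	ITSMSLCTPGCKTGFLMGCMPKTHTCHCSILVSK	GASPR	NA	TRUE
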