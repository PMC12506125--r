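>lanB synthetic reference protein
MGDYESQSLHEDDAYHAPMRFSMHDYAEDIMYGMGDIFHPSHNLWCELQVKGPSGYLWPASKIYNMMVKEENSWMYVNMAFFLEKQLVNVNMQDIEGQEFMDCHQFISNEEQVEFWSKSKLDMVAWCIQGYSFGSNKGKYTNHWIIYRLQWLRDAGPWAAGLQFESSFTKQARIHCGFDKYCNNLTHREVCNTGDNSICVLNGYDNTLDREKPFYNIGPEKCERWEDCKPHSKGWPHWPTIMVCQQYPMLIQGSNTDWPIFTWSQPMGDQMKIPVRMDEY
>lanC synthetic reference protein
MTEIHAKPRMIYICHQTTKWGLQIQAIPRNFGQNFENTTENALRNRMKEMAQKVDARGRTFVAGIPLWPTIECPKCPDCHMVNEQWCPGSAGAVIIPNNNLVNVRERHPGLHSGCYVGPHGQGCMAHSIYINGEKVRGRPRCKEADRDVMTYVFDPSFPWINWFNIATSLRAWPADCNMNADDKERVQENMAELMRPFSS
>lanI synthetic reference protein
MPAVAVGSSWAAMEAIKHAGALAFNDHTASLFERGAVDREYPPTRISIRMNMCPFVSYGTHFQTRRHDEMHWWLHDVFMFPRKQYCRMYV
>lanT synthetic reference protein
MTSPQASFAFYSCFIWKYWYADAGWIRDRMAFEKMQTMCSSFEKAPLSIEPYLDDKHMMATIASNSLIWVDGNKGIGYCDYERTYDCLVTNMMTASYPASCGKRNDGALQWGDGHRRNWWVERLPWGLCHFEKFFMTCAYWQVLDIHWCCSNESPLDPWLMPCNFEDETTFTMHEVRGKV
>lanF synthetic reference protein
MQCMKYKRFHYFQCVTPLEQNINQAAFQWMIGFSDDGVMMHSDIECRHGYGEWSIMDVLTDQRKVCYQDPAVVNT
>lanE synthetic reference protein
MGFAMFDVWSACDQKYAKTQKAHFYKYLAWVETVTMFAVMGPDMAYGIWGCVGRKCNPVVWNQMCYWTFNRFTAC
>lanG synthetic reference protein
MELSSAGDPSLYQTQYTVTSNKMAHASAASWSSVWPGYIDTDSYRRGNQAAARTDPKPNTYCNYPHIIINAFFCW
>lanP synthetic reference protein
MHQVNVANHRLFATIEHTCAQGFGQCHTSRSPNAHLPAVRSGPNNANAVCTAHMKYSGRHARVWDWQWNRQMNHRNTWPMTFFYNCNPHMAHDDEFEFHGMSTTATLWLNPAKQVTVYSRASQRVNRIYPAFWGFHFTSRTHEPPFMCQTIVGEHKYAWN
>lanR synthetic reference protein
MYKVARLRVPHCYMMLHIKSWPHTRCWNIGSPCMTIHEKRPLHKTKWKGAMIQGADEERLGNNVPFWWECKHQCASLGLDGNEVT
>lanK synthetic reference protein
MGSWCRIQNRVHCYASCICAAVFCHGILKRESDSVWYLTTLNGCQGLEESMTHDGASHRQVANVVETNEFFHYMEKCDKRFSMKAKVKELLVWMHMWQQAMAYPLKNEYQCRLVQNECSVEPITKTDMPN
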