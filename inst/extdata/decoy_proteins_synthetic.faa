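>decoy01 synthetic decoy protein
MIVNFPTLYHIMNVICPFRKNKTKDEESTQKSTPFRIMGSDVQTAEFGGIYPCTNPRDEQSYGWGQIARNCQVWVTYHTARINMCDQMCWFQRHTTTTWNLCPTETGNAKVECLDFQYVSPKPYPSNQVYSSGNEFFSLYVQDLTGYEMQWMKKKERQFWCMPRNMTRRWTKIRNIGRIYCLTEGPWTWIISKSMHWTDMDQYTEIESFQCFVYCIEHPVQLIRNAADLCNPPKNEQYCSPQDVDHSHFHQMMLNL
>decoy02 synthetic decoy protein
MMRPQWFVSWWKTKQSCHNYFARHNWAYECDFVHVFNNMYWSKGEMKEFERQHIVWREGVKDCQWEPDQPWYCDCLYFLRAQTVKMWFIAKWNCLVRCEYRVYIMMPMSPEQDWFQMSCYICDREPQYAYGGGNNNCCYWIVNDACYWRMVRMSTEKELQENHVYKRALYLPNSPCLGNYFKWDYNYVTHPKAWTPFAMKCTLGAKHQGIDELMSMYLNTPPEIKVEENHDSPGQNFTTESISLFSPQKSYCSPAKVETTIYNLIQDCPMHDTLFNDYCNRQKLNNHPENRWRKQTLQRSEPDGDPKANWTQMYVTIMYSLYRSETNHPTIPPVEQSSARCVTVDC
>decoy03 synthetic decoy protein
MIPDVTECVMMLHQEVNLFNCCRDSVWREHNLFGYTCFDQTNPFCTNTGRIMMFIRDVQHHNPFSSFVYSRKAIGRYACFISNEFDWIIFPKFISHPMAEKNHVCQ
>decoy04 synthetic decoy protein
MAPDGNCKLYKKWYLDLHRNKDNGVLTVPPEGYCNKRRKPCKSCIELADSQVQPEINMSEQCTSVDSVKPTEYDFYTNRAMFPEPNFIRGCAMHDQHYEERKRLDRVWFTHNDFREVHCMSIIVASWTAEPWVHTSETIECSPTFIQFRKWHTVSWNSQDLDQSVSGFMLSPFEDRLNMRIAAIDSHEPCQHDTWDFAKQRGYWAALADNVFRAVVANDMSWPFQMLTHIDHHSNTTTQARRPGAEFLWRERKYRWIEFLWNVAPNSMKNNNLYRKMYNTTFKVCADGMTPLFKASHLTKLIQRLPLT
>decoy05 synthetic decoy protein
MASNQGDHCKPEKLMPCFEDEHYMFYDVHACCSGPLRNTWVDFNWRIWRMMRYICGVARKGFTNIFVHNALEWLTISIGAMPCTRQFKFPDEIDDDNMQEMTRCMGFITCGTVKMRWNFLIKYCYDDSQYISNLIWSEGACPQGKQKNTDSWVTGWMTENMWYPTFLKLDLTATSDTEIQIFVKGAMQQHPHFNISCHYPFYMFEMDWQEVQKPGPLWQRRDDPIGVDRQWVMYLVMKNIKNLACYGWKIHDYPEPNWNVENASRMFAEARCAFTDPSDPMPGTTWPLINILDVWDMCACQQRHGHMHEPQDMRGGGSVAESWFIEHPPIEMACKAAIHHDGNMKRFDAANHRAQMIIPADSQKLPWHCCHDEMQQYKQQPIRV
>decoy06 synthetic decoy protein
MICPRLCWFACTCTYNENIFMALNAWRTSVEVQILLCGEPQFYKKLCMAQQKSWVKYEVRLHFDGQSMVSAYPWFWHHPRDNPLNMMFMRSCNKEKFFAMAELWIACQMGAEPVDLRMRCNECLVRLMMVHWPNDKEWMTMTVAPIVPKIKLQPEPMNCQTAKYLSEFVKMFCPIDKPHRMMRGFQCKVNLITGANLPPLGHFAINDSIFVLINIADNSKIERWEMGLREFNFQYTAMSRGPSYVLCFMMAQKNGGDHGDSKGAPCSNEFNLNGRGCDVSSMQATNGAKLGVIARMSVGDFGTTPSGKLRDVLCSTHMFIG
>decoy07 synthetic decoy protein
MKQYVTNRQRCAACHHGRSGHLDQEVADFMPIPMYYKMSNKKSGPYNLQTHAVILRAKGKQWIRDQGTYMQMEIQHKGRKTIWQYHIVAYEQYVGSTLSEWLKMKYHEHPYHMSFSSNLRRFRNMRCGKKAIRCCGSVMPHRMYQTVNPACPDCRSMRDQMAVLCLCGVFTSVDNMECKVTLHCMHVQSQLVCIKMGFQADDRCQIDHRARQEQEGWYMCYCETKKPRGAYAVLDLKGCFSGMIHRMGFEVNTYRVCLNWHYRMWAEVDKKENKLDLLKWCLFCFGFCP
>decoy08 synthetic decoy protein
MVTEHLHQRIIMWRCWIQRKPDGCEYVKGCFLAFCNQWFQVECDCWECDPKGESVPWPRPQSFEYLVTMWLMAYNKLLRKEWIQTAKWPNTGDYTLTMENNETVVALIDCRMEFVISAHMLWCTQMNLKNGFMMLNVTWTVGFVFKSGHPFDWDDCKLYHPQQDHKWMNKCVRWYFHRFEQGTGCQKICMMKYIITVVETCKWSSRSIWAIQLPEACETQARYSPCMDMNTHVFVQFAFKCMKQRPQDIPSEKSHHTVIWYRDISWGWVHVSMQQTALLQFMWCIRNCVCSIWCCGNQVLSYFFQNIKMMSMDIPRPRNAFIVSEYVHYVCKICIWTYASPPSEPYQNWRTIKLPARNNNLSAINRNENQDTTCNWCIWMVWLKPNMILWRPIWGTKA
>decoy09 synthetic decoy protein
MYKIWNIICVFTIIHRWSYGWKSPQSLMDQDWDGMEAKCYYANDWPCEIDRIQDQGPGFAVHPEGWSFLKDHKWNHDCANPHYTKDDESNFVKKMIIPTMLFDRFWIRMLEGDRVIKPGEFVNCAEDPPWSHEHHRNCSETRECYKDIWRYGFILEECVWVNRWFGPKQSTNQDNDHHQSFQHPHPSFKNIDIVYMWVQYENGTTQLPAMQKVVCNDDNFFCVADIMSLKFGAAHDSICRETQPPKCTCDYMTSIWITMNYFILVSTGEGYWCDWRRYVVWVMGVGTCPMMWGGICGLI
>decoy10 synthetic decoy protein
MMKRHFVAEWVMWGFCQVGWQDVDEYSWAWHGFIKSETFNQASPESCQHDGPVVNWLVMMNRPWYDCHSGIKSCWNGMLQLHWFGFHQNAWTCLYDCTDSTDTIRCEEAVGTMTYMNHRCDWNINIIKHGQVQNTMIERCLIPGGMWQQMKDSLVGGTTFDGNFADHLKLIEKANMTCHIFDIEFKGPRAMEYWNCEMKEAPS
>decoy11 synthetic decoy protein
MVSEPTMTDGSTHDTSRRIVFYHIVHGDRGQWQYGIGDYWEYPLEMEPDWSFFIVTQSGYCRSSTAPPHYVGTLFAWFRTNHWSAFYWRMFGNIPEFWSQLSPLANCTFMHHKPSSKVGKIRIYISLQNAWHGMPHMFKPSPREPSLCNHGLGAMSIFHEEGFVGQSFWIPIFWVYLFYVYSVTMGQHQQWRNDKDAPHDEQVSDQWFCAWQNNQHCEAKDSRNNPAELQTDSANHWQLTICLLKTFCAKTMAHPFHTIHQINSATPPLTNGCVGCRMQQMWDYYSEARPLNAFLIQARLF
>decoy12 synthetic decoy protein
MCQFSQQDARCEPNARIVKKQDNCTDGCRKMWNAECHYNLVMEWNCRHWCELNWHDCYLKTYQFFENCPGWTMGSTMKLECHQRLLLNMDNLMEEYPTADLVWWITIIWDPFIYGGGLPKNWHEDRVICPIVENPSAAFYAETGYRMMKCFEEVRGFITQFDWEGTAPEYIICGSSLANTVVLHLESLSYERWLPENYGGDQEKYHTKDWKSSNKTNNRMPKAHCWLHLDCWPCNLWWNQIGRTAVGNTATDCPLFYHAKWWEGGNIYCGWVIFAPDTKIKHSLYSEFFMMIYHMNMIGWCADFYHHMAAYAHTRITAESIHHDSRNQILQTWPFFRPHFMCQRNQCNAMTRPFLTEPKDTPTVWSYPDEYIKQMCP
>decoy13 synthetic decoy protein
MCRRQAIKERCDLKCESEYTYLVISWPMYFIAHSDGMEREALQAGWRSMLQDHAWETYCRAGYTITSDFNNEFWLDGTMKKYSMDNQAEFSGAKADLPTSNKLWYYPASSWRWITHMVQWCDEYFFLVQDIWRKTDHHYAFSFHRHAGRQWCQCFPPPMYIHRVWIYFHDVHAITGHWSWRF
>decoy14 synthetic decoy protein
MEQQQMWCKNPEDTANRVLNPSSEKCLQNHGFQVWEMDGCQPSKLQSLMGISEFGMSDKGPYFKWENSNNRFQLDKGKFACCRMCMNQDYCHYIDFHQYPVQKNWNLQYPGCEFSSPHHMMHTAWCGEQAEHRQSQQLVSGLEFDRTFQIRHEAQFFHMTMFVREMKGIARTKWVLKMYLDWMDFLLGWKAGKRRHVMNNSRNTEVYGTNIYVNWGSNFATGCRIYGKLETVKDHWERFFMMIFFCADHAKHALWNFLNMSNYHNHWTNPSGTPTFNSKFLNNTFSCSHQYRVGHEKPPGFVR
>decoy15 synthetic decoy protein
MLCITYHHCLQNERIWSQLIYVWFGFSWHPGFGLGFKPFWCHVFYMGRECYQVKDTASQRVVYNIPCYCLMIDNFNWVCGATQDLECMHLPGIMCFGNRIFIRLFDWYEGDANAMHFEQTTGLTEGTSWHLPNCYMIEIYVCIHHYPTKELFDVRVAD
>decoy16 synthetic decoy protein
MCYWFASWVKWYTPPENRSKFNSIETYSFHYNPNCTSFNLGFWHQEMCLIGWTCNFHGQMPCNFDKKECELGRRIIQMCTSRGHNAEIKHIAYNFEMYQKGHENHYNERPTPNAYKRKLAAQNRCQVHGITIRNSLLMICVQSISFPTVMYHQHVKAED
>decoy17 synthetic decoy protein
MCQTYMHYAWHNTDLMYTLCQDSEEFLTVECLECMHWALLTFQTHPFLMPGPAKCDNQFWQYCNSIYCWHMNVMAPWLGWDVEHENIMPPWNAVEGNSRRNGHTMHADPWTQEPGYTTSAAPDRGFCNYTDKSEMSQETCAWCAFKMVESLLIYWKFAFTHTKSGMQDHNNRWFVWNWKHKGPDIITKRAQDEDCITKHCHNYGNLMWWRWAFASITQLVTFYEYMKPPAIKADGWPQGDIEIALQSGRSYGPFITFTQMVTLHMVFNQCDSQMHMYMHFAIIIHWLDVYHDFDFKWLKFVKINNYHQYIFHYKYRLNIQYKACEYAALDRGFNCSQVIDRREF
>decoy18 synthetic decoy protein
MMMGASGFMKFVEYEEQYAHKRADSGTKCVGLVNHLDEFKWWKKDSGWLSRICALQHERGVGHYCTQPVVTYTETTVVNKDWGKDTIRKQISCGEVDKMVNWIAKFSFTKQMYKKQMEMWPRFKWWMVSHSESRYKQIAECAYQLTESGISMANFHCPAPKTGLVLEEYQMYPWDAAAVIWCSVINSPTSNHRQGTWSHCMHKRRKDEDVEGMIWGCEYNSGQCLCGGTQEIKVLDGNEMCFFTWSVFKDGTKEPRDCMFSNTPCRDDDHPILRAFKIEDCGSWGA
>decoy19 synthetic decoy protein
MTPDKKDWRAHCNETQLDELHCNIMGMAIHQCKLSDASNQNTFWQSTVSHMRLWDWKTLLEFKAIICQARGLCNFRMGVWMKICCDWASTNSTKLRSTDYGSAAKWQNNKGHYINWWISIHSIAPLPLSPLIHCYATCEHMDSRTGAMPQWVLNELSGKRLHVWTAFIHGSFRAEDFLDVSITWHTLFQLYKALAGGLPLSQRHRDCVEMMQCPKWNRVGLIPVGMQPFQTGRHRCAQHACFDLTTDKYQDKYMHCQFNFLSAYTLEWGIGDWFTAEMGFKKLLRDKIKGTVFRSRVWGDTKDYDPLYELWLT
>decoy20 synthetic decoy protein
MFENALDQFRPKGIEYASDIGQQSCPMFMGISAGVLASILDPWIKIPPPPNCTMTSQCMWWHAKQEMPRFPSEGNCPYLNWGVMQWERISKGMHYSYYCPCGYSVSVVEPYEMWCFQFNKQAHVSNYTTPQEADLRTFMWNGNPRGIQLCDIPKNMLNMPDAWFQTWQRYICKIIDTLMYSTCSKYRWGVNLRAKQTGTLMVCNQWGKIMWEYHKHPGNYGHAVQHYYWSSWSAGYWMVTGWHQTSESDMCYSRSNFMDGIAPIDDYNSMQYISWWVFWWVVYFAHERSMWPAPEHGMDNGSMLEIDEKLRHLLEVGAHKSADHGTDFPTAVNSM
>decoy21 synthetic decoy protein
MWYQSMHCQEPFNWNWWAAYCCSNQLQESFFQRHNATLQYRSIYASFRPDVLSYQVCTGPGVWGVQNLPVKRCQPFRYMNVGRWYLTNVYHTVHFIKRNLANSIPNARH
>decoy22 synthetic decoy protein
MHDDGMWCPVYTDCMNHAEDPGICHFECNQRWCHYMNTARAQHQNKAECTRWGLSQSAERCDCTTSQWQPVEVCLIMLWAWYWICRRCKIYYGDTHLSRWDRNNHVHGCESSSMKMDGGRWEREMVLEFKTGRTAMWCCHPCDQDANASDGRLHRYKIQHELSDRPSPAIGAQHGGYCQKYCFVVGQGTQMCHNFAWQERHDYWGKCWLCPYIAPYYPARNRWFSYMTCNNYWWVKQKVVILYDFTFRIADLVKRDAFFCSIMMEDLVLVPWSCFYYCSKSGHKLMTPCLETKCFQDASRECPFCHGIKFQSFPTGKMCRNETFLDCTDWELPYGQYIMDRQCGFDQSEYVPRYNSGSPCMERFDFISANCPCTSDMISEHCLTTDWSAEEYTTRW
>decoy23 synthetic decoy protein
MRETNGSTPQFFGRGWNNMESPTCEMKRILDIRCGSAYFFNIDHPMCRYEPHWFPRIMKVLSYWMNGIKMVRMLDFRTVLAGYWCRHNYADPRKHSHYYTGRQCFWKSEWCLWRQYQDGYPIIWFYHNDKHRHTTQEHCAHAPVINHVYEPSTHDWRGIWPTPNAQARIDTHEMQMTTFK
>decoy24 synthetic decoy protein
MGMASEFFVFAWDNNAIYQLYFASYYFQQPTRNTRWAPVTYCATCCIDTWDQRVQLIPAYADKYCNWAMKELYNAHDFDPVHPRLPYEGWNEEFNFFKFGNGPYSSYALAWHCRRDCDYEIDRWGICCVAPNQIFEIL
>decoy25 synthetic decoy protein
MMAECFWRHLFSCKMSPWWKHFASQLDRRGCSCMVKQVWRQVSVTGPTYWIPHVKAAWVYDEVKIHHMVQYAPYLRKVFMNDMMDHAQKPAWTGMVEAWNLLNHRAHWPNTHWRTRKTFSMTSSKKCRMKNNKTW
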