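>Ecoli|cas2 synthetic reference
METQLTCHLAAWKGQECWELVSVMSVMLPADWIGVWMSHWRLPRDVSEPARWCLGDCKPCFDLHQWKTHCYYSHSIRECM
IAVTPCQIWRTADI
>Ecoli|cas1 synthetic reference
MPVNDFLWYKRRITSKSKQHMHEINRRTSVPEWVRSWCTAVSTLNMVLSYILKVFCAPSCIVCDPIWLWCELSDNLRPLT
YGSQPSPYSMVWLEVWGRGENEKFNITDQGSEFGCNDVGKDVNKDDESYEKKHSFTFTCMPSSRVQAEGQFVFHDCCGPL
LMVTYGSLWFRQIVQWEQYPGPYWVIQELQPRIFQLNDGFKGESGGGPKPLGFDWKVLKCHFPSKNCFRGGAMDWHIQPQ
RSCRVYPTHYMWQEYILSPHNDTMHNIKMCNANTAQLDFSMVKAWSSRAQPSLQVFFYHSAYASS
>Ecoli|cse3 synthetic reference
MQYLHEHAGMNDRNQAIYVDTVWYDTTTPMEYGFQKMMFDPSDRLRAAFYAIVWNDEYDAVLNACSEDLKVWDSPWLWQY
EDWWDDRHNTGDTYEHRNSNDASSHFYWRAMDDPVWKNVNTPAELTITPALHECGVIWYDRDPWQHGTYMTTNREGKYKE
LTGYVTFAQDKWQQRMRFFCSPKNYEVHIISGMNNNYIT
>Ecoli|cas5 synthetic reference
MDGYKGCPPVPVNLFFEQIPEIMIVYFDMPFGRAYMVYCRRRCDKTVDAIPKTACDEARQFYYNCWPCIKMRNMTIPDRC
IQWWVKPDTCMTVYVRPRKPRIYMEPVFVRFAANLDGEHSLFTEEVCSPVGWIPEYLFYSMRPAANSGQEAMNFFRNTVR
DFEWECGEGFAGQCSNLCHLPNEDEGAKQKQKGSPALEDRVEQMVIVKCKRHFRWEYQFLTNNNPWDQKSSV
>Ecoli|cse4 synthetic reference
MKVNVNYWARINFQYKLQDQMHLCDIKSRHDSKLTTLLQMHVPQHIRDMRATCEKLVYMHRSYKDDFDYFGWSQKFNYSQ
CFAVSHKWKSEQQKHPVIIVKSYDGDELYKESMAQKKNRQRRWMVAGWWNIIKLPTIDMLHIKTRRLGKQLIPDNKYSID
VDTEYKAGWYGDLTIMPRYRYTPTWDMRSAREAPTKLKGISLSTANVNFEFESPKGLREWPRSAPGPFSRSAYEYNLYYY
EMCQSKMGLCWFWTYHEPTFAMVHSINFRCFGYFLEHSWCIRYTWMVIDGWGKNAHVGDMIMREAMRGYCTLWFDCYVML
LSKRNHKFMPKATYGRTQRYLATPGPYNIEAFWTERCDCLLTFNDYQRPCWKPDVPYNED
>Ecoli|cse2 synthetic reference
MSYKLKDCWWLCASYAAKYTAAFTWHHMAAAIWCHRHDLTCCQEIDEHDWAHIDSFLGKACLTNCATDWHFREGYYCGLD
NIKHTVAGNDQPTIQHSFRFTPIDEAFRFICWVCDWHWTAATFMKFADDVWRIMDFYYSEIPEYTMSEWHEEDQDKWWMI
>Ecoli|cse1 synthetic reference
MNENHRLPWDIWDARVEVEGYNHASCALWADFWINMFAHMWGIQCTAVFSGCPMGCLKMDCRMMKLHHNMNTKPAGAKIP
MVEWTKWLYKKGDWKCEQPEFYNLSLWRVKIHDWHWLRSSVMTHPCKVCEIPDKFTDIIYPYQDVRRNKMSPCWWMGYYA
RLQAWGVMEEGWVWFWLDQWPFSQAVKSDSFQMRVWPWQRRGYDWWFWAFGFMHVHQQQCCVWFGTMMVPIHWIPCWCVW
EDWAMWNGIVILLWNTNNGNPAIGSYQCHQDKMAMHYQDVSYGRAAQWDGYLSRCMLWLFNACHLMHGEVQDIDGMVHMQ
LNDRPCALIFGLHKLVFIPMLHMHFEDQMQNMLSSWYSPQADTFCWEMRNRRMGNPWETPSSSRQCEEPHKEEMWECHQR
WVPAKNDVKWDALMCQSCYYIGIAKRDSQAVYGQDDYCTHKGRLKCNFRGRQTQWSGDQKGDCHCFCPFPDSIKNYSGMA
WWFYKCEFYENCRGRGTITHYN
>Ecoli|cas3 synthetic reference
MQCQKGYCQSGAWNVTLTWSYSIYNNLGPYRAPKQWTCLSNKTHWQARNQDHLERQDGETQMYSGYAGAAFWCSPCHPRD
HIFKDVWTKITFVMGSMRVTTMRFKAMDHCYGSQEKKDLYAAYIYCTMKAGDSFVCDNNMGNMLENDFFQDALAKNLSRQ
WRFPRMTSLILWTVFRRLYFKQNVMGRCMPHCFVVGCYIFDWHTIDRLHGWMGLVRMIKLMIELIMWENRNWQATKQVYG
TFNPMPFISLNPCKCRCNKVFFDYAINKNKLCHSFQMMFHFYGDDLEHMACTFELVADWSQNVFIQQMCQMETGPRWHSW
VSITTCCVFRYLLPPKRFTGCSQNQYCAFSSGHLHYVVANDCTAKNVDDAANHAFESPKQERNPNPIINPEDQDSDNFAT
NLKTTILCKTITRRFSSGHHPSLFDYWLDKWNATIYWQLCAWGPPGNTDHSHQEIEVSYEPNVYPCTVEYSYMVMGMIQC
SIPVNVSYDFKAVMPVVGEPCGTLLGARYLEADMREPHLNARHEIHRDKHFTVFCWCMTMCRRFQWDWCGFGPSQLKCQY
LKATHGCRRSSKPDSNLPKGREINVAIRHSWAICHSVQPIYKVADFWLWWFYDQIGPKEIEHERFWWRGNTKANWFGYWG
NYCYHQIARGTYCIMTLTDGITHLQKCSQAFNCDGSTLSLFGQSAYYLHFGVCCGTYKYDYVLHISPDNEQKWACINDLM
HPKNVVRGIIMAFTINYWVVLLMEENSYCWFKTMDPVNWMQSGDQTHHTAVNEACTSRVRTGWWIPCIIALRGEFHKACS
FPFAASFDMWWDIIYCILQIVADGAMQETEFANGFSQPWETIVLYQAIFSEGWFLKSNHPMWVDCKPRFIGTSVFHDSKF
QDPQRQGR
>Ypest|cas1 synthetic reference
MGYAINMTAICIWWRYACWCDNCVHVRHRLDFYSMKYKGGFLDQFHKLNHWPPLEIRFFQYWSFRQQTFFSASNKDDVKD
HDKDYLRMIWSDSHWIATCWCDKYIEKMYNDWYDWMRYYETGFHMCTHDKSDYGVTGWSQNQMAWCNPTWHTQAMACHTK
IRVSYVWPSQAHHCCGEPPDMNYKEFWEWTNTVEKPNLSPQDTAEMEGFVNFQCGSTPTIDKDNSGCSRIMKIAATFPRM
GKCNRMNIWSMVCLWTIWWVRNSKDTWAAGEGNGHMGARHWVNQKRGCAYENGKIRMEGMHRCEDNRNTSWAENQSMWCR
YLTI
>Ypest|cas3 synthetic reference
MPHLWNNMKMATHKTSALCSLRPEPNANYSNRVQLRLCWGMWICLWAWNKGNGSAQGRCNRHHCDCKHQIWGIQYSQVDP
CFHKEKPTHCCKHSIPLKCDVCSWATNVWAACVMGIHIPQGCRVLEPIGWYQNRGWCWEYCWWYSMREYKVHVAMKTNIF
SFKNMWWFHVHDWPLHVPAFSCLFEHSFQNGPIMYVRYRHSSYEQGENSKFPWRIEAGEWPFLSHHGVMPDDVFGTHLPP
VCVCSSSMHPSKSEDSRQQCGEYLDHAWFAMDSNWANKMDYATINFALMPFYKWITLIGIKCQENMMELWWPMLCGILQF
SWNYKWFYNMCAFVKDRPSYWGIVCADQRQWPETSRNTGDKTVKDMPLFRIIVFGCGIDHMRNLFWQHDGDYQWLKILAL
EMNNWFMYIFSTSSVMRTYADPGFQPMLLKEHSASVEHYWIKLAHGMNRLFLTFNCHDECKVDLDNEVFQCRHAWRGPWH
FPNGMHMSWHSTKYHSDPDQPKWTGRNFIVAKQAAAIKSSWGQACLQRPKRSGSYNRQMMMWSRYVTCICVPCDYSYDTV
GWGFQRHRQVSPHIYYKNVVMYDCYEVHYFLTEYDRQPVPNHPNKNLICLICPVNTVGAWCFMHWTCICSEPEKWFTFSR
DCMLNAYHNYQRKDKHCMFSPGKAMQATHGQTYWLKKVALNAKSCAGLLDVFMAIICNYD
>Ypest|csy1 synthetic reference
MFFSLNHANMFFMAMKLKEVAAACSHFKLKVDAKMDCHEFNRGPTVCVQSPIRSHEEWYLDTEHTIDPHNEDKEMRDPFY
TQECTHFWHYMRSWAIKASLIYRHEEDDRWRAFLHHYMRTLSGKYGPDCPRMWCQCKRLFGVQWGQWMPSQNWVMGGRMY
LFCEKPAVTVVPMHMWGIALLQMPAFYKEWVAEFHNYQGCMHTPDKGSSSITDFPWFWHTWIRNTINYSPCAYWDGKCMA
TLMLPDFTNYVFCVVNIPCERQWCILMQMTSYLTHFTKAKDLISPGHVIVFINSGVAAPFTQGCHSVSGSLTWTGQMFFN
IMFMIILLHQDRLECGLPPFYMVPDMMGWWGVSFGWIGFTTEGKLKDRDCMHRDWNQDCPDIWPWAKKKENIRGMMLPCA
WDHWQYFFHARQLQPNTYAPFMHDRHWCNQEGAQSTRFGKG
>Ypest|csy2 synthetic reference
MEYLKRQNVVTVIGHDFTKYESSLDTLYYMCLHWNALKLSFVFSSAQCYPWIGSEAKKMSVPPNAICPVHIAVCRIIPLT
RNGHVFIMSKWFTIQIAGDPCKPCNERSSFMHEGTIRQYMTMRHACGNGYGDCVCFRQPCHRAAFDCVMHWFHWPWTPIN
TLFEINQANSSEINQSPLTDMSQVMHWVRYTCIGQKVWHGENINKSPQDCEVHKYWYDLTIIVTVEYGATMEIPLVHEMR
CMHVSGATQGDETWSTCIYVGIEPGTFYFWNFAVPYFCCKCHEAGEQIFFYPSDFFHPWKMMNGPWRGQTSPRWVRRPHN
IHWWSFEIVLIGGLESA
>Ypest|csy3 synthetic reference
MHRRTLNISHGVCLYMMIHNGYDAFRDWNASYMNHDFWCDTRAHNPWAKQREQLIPGDETSSLGVHRMMKMFGHMRFWAL
IKNEHRADQKVNMFRSNDLMHMRSAHNRGIGTKAKPQVPPSFFADICDFFSQSPDGNACGSGFPNCWYPEMWTCHACADC
PCIWMYNVDASTHMTVGALWQYVLMKCKADQFLFHSTCWKICSSSQNAKKDCGWSMKEYLEQCTQQQLGVDRWTSNPNMG
NCATFIMIQWHRWQPRNDFHGLFWFISPNPEDLPHWAIIKIYMHMVMKAFHIHLQGKKAPVEMLKNTHFVCVHGGFNTRI
PGHIPEMTPWSCVHQWLTSACN
>Ypest|csy4 synthetic reference
MGGEMKTSVYVNLPDHEHWPFVYCRPVDGHPRSKRDAQNLFMDWTIYGYLILKSRVADRFLNHPHERVYMNTYQFGENGS
GNYGARAINMNIMRYLSFGVLTSLYWWQRRWNYGDYMHLREGRPPGGPKGQQRMYYNEQEEAALFAVEKTIEYSKTDIGR
PYDHDVLCFVMNPRKPHETQMTKRYT
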