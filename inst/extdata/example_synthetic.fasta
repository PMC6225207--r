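>synprot0001 synthetic example protein (motif planted)
WRMNGSHAQVVLNKLSKNGKAFPESELEANPGWPLDWNMKGEHKFAMSYAMYALNAPQKK
AIDEGRGRGFGRSRGSGGSGGRGAGMEFQKKAEQYDSRSHFQGIHDEAGCAHL
>synprot0002 synthetic example protein (motif planted)
LWRPIQADSNERYCQDHQEDMGWRGRGRGRGGGSGGSGGRGRVAEFSYQPAFLVTSSKFG
GGQTVATCSRIMEYGGMARTHALQRIQMSCTNWWFIIRQYLHHEGAVDPDNFDSCNECTP
YWKSIETARNTLAFH
>synprot0003 synthetic example protein (motif planted)
PSLPSSAGGHNVYLCVNPDLWRQLDVRHMMGPSCPVGPSLVYDQVYGANFLIHIEELVWN
AGCRGRGRGRGGGSGGSGGRGVGWRPNSAWTAWTSFYTVHAHSY
>synprot0004 synthetic example protein (motif planted)
SEQCHKGVPHMGLPHNNRGRGRGRGGGSGQSGGSGRAIKSVFEYSNLVAGESFSAYFYVA
WGNIIGCAGFGSEHADNPMPDGMASNSNSRTLMEI
>synprot0005 synthetic example protein (motif planted)
WDNVLAPSLKHWHTIPSKFGWLRRCHTSIYSNNFQKLYAIKKNGFFILNEGCFRGTVAKD
PGLPHSSESHRTLRGRGRGRGGGSGGMGGRGKPFLNFSEVVPSSKINSNYTQLCIQQCLW
SNDIDRRHDIIRMTGRAWPNLQELASCRCYFRMLEQIWQELTDIEVGCTEVRDARTVAMC
PKAPSPKEDDST
>synprot0006 synthetic example protein (motif planted)
HITADIDSAIEFLSMVDRGRGRGRGGGSGGSGMRGRGVGHLNEMHCHRMEKNFAHAGAQW
YHMLVRPWATTLICYHLMVTNERTGYLNRDILAPLRTVVVWKLEVCKQAMKWTRRR
>synprot0007 synthetic example protein (motif planted)
MVFEIDTGNMWQIKYLVSCLQHQLMKLCHLVSTKSSTCLSWWMLRCALLICVSERGRGRG
RGGGSDSSGGVGRGYPMEYTRWSVVKASHFPRKARFWILWYAQDLRGLVYPIECTYYYNK
TNWDMSTSAWHLLVCLSVC
>synprot0008 synthetic example protein (motif planted)
ATFNHNGGRLQLLFDNHHMMNVSEDLSSVKAALVSLYQLMRMREKFFIHPKDDDYIVSKN
LCKTACDKVHISEPQHDHGLLLMNHTLFLCCCDWFSYQCFTACRYEWMFHYLHFRFMHWK
VQDQQITRGRGRGRGGGNGGSGGRGRGCSERKLHGVFKIHAPWDFVKFSAEQEEHWLGRM
AHPKQVLREINCMERVY
>synprot0009 synthetic example protein (motif planted)
TVLWSWMYASCQCKSASVRVEYQVGCKGFLIPNGALKSESAGRGRGRGLGGGSGGSGGRG
RGQDQGKNPTREHDWGIQCHNVTCYYKMTEE
>synprot0010 synthetic example protein (motif planted)
VQLEHPHAMPYAELRMHWFRDDNWLVKRLNEDYEPMQWYRHSQLWTLWYVDHTSKHHKYR
AIDHKYDGMFRIYAHARGRVRGRGGGSGGSGHRGRGWYCYYAMPWTVLLWCNLDGLLHSF
STVWSLQWYPEYSQGAVGHHAMPWVGYNIFAFGCNPAALVLRFG
>synprot0011 synthetic example protein (motif planted)
ACSAKLSNKAGKKATSCRLHSVFPAMLWHDVDTHNCWTQKDNLAWKCITGLDERHTCGAI
PIDKARQFMHYQYEFCEVDNYPIPFAAFNYTEDLNNYAQLCRMGCGFRTRCVAVPEHYRN
CQIHFEVPNLKDLFTLIRGRHRGRGSGYGGSGGRGEGWVPVLKRS
>synprot0012 synthetic example protein (motif planted)
GDPDESYVYARFMDCVQLLKTLCNIMQSRWSATCERFSWPVTMYHKLVLCADSRAPHNQK
TGLLPMDPGKQTEFSANCIHAVFFNTFMHSLSVLKPRMHIGSFLLESFDDRCHRQPIYYF
RGKGRGRGIGSGGEGGRGRGV
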