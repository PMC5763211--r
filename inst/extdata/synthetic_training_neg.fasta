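>neg1
PSLADNKKIAST
>neg2
RRYEAAD
>neg3
TPICIFG
>neg4
CTTEFAYCSLCK
>neg5
HYKHTCFACSNK
>neg6
AMASRMDTICQE
>neg7
QFKGVCFYTVHE
>neg8
LKENSEKGWEVV
>neg9
THFDSMKQEDRT
>neg10
TVWLDWHIVPRQ
>neg11
QMPVMDMPYCVD
>neg12
VYDPCHFPDLPN
>neg13
FSGPYGVIFNFG
>neg14
FAYGKDW
>neg15
PPSPFNM
>neg16
MLDYILK
>neg17
PFIPTWS
>neg18
CYEADVKLANQI
>neg19
ARCKNPNNPDDW
>neg20
VPIWDRD
>neg21
VFVMHPR
>neg22
RGAYRHA
>neg23
PRTSVVMFALTD
>neg24
VQQYVMS
>neg25
HSPWCRR
>neg26
VHFFCED
>neg27
EDWSNHE
>neg28
SVCHLIW
>neg29
KCYVAQEYEPFA
>neg30
HTKWEYY
>neg31
NVYPKFW
>neg32
YRFAFARCLGQY
>neg33
EKDESFA
>neg34
AMSSTWSGMTCD
>neg35
HIQVDHS
>neg36
IWGPFANVQWRT
>neg37
HHKHWSWSSAFT
>neg38
HDGIAAL
>neg39
WVSQVFK
>neg40
EPRCVFRTAKNK
>neg41
VRHLSVDHEGCD
>neg42
DLEYCMT
>neg43
TAFILRR
>neg44
TTRERFPQFNPQ
>neg45
NGHVLRY
>neg46
MMDAFNE
>neg47
FREHCGSCSQLI
>neg48
TGGRMPLRQNHS
>neg49
RNSARAA
>neg50
EFYMKIM
>neg51
NYIICMK
>neg52
NVCSSWHEYQQI
>neg53
VPYQGVRLECSD
>neg54
FARAKVHMFSPG
>neg55
DIQFCDFVKDWN
>neg56
HTEGQWQ
>neg57
WYQDLKAMHSFI
>neg58
RMCSIRKMPFHW
>neg59
VPGPTEREWKPM
>neg60
VTRGASPAYDDY
>neg61
YFHCLQGCHVSN
>neg62
RLPLYMQPRYCI
>neg63
GKTCQPP
>neg64
STDSWSR
>neg65
VYHPCLI
>neg66
FVAFIMLVWMSR
>neg67
AAAPYAA
>neg68
FDLCASV
>neg69
VNWATQAKGCKG
>neg70
HHTLRANFPRKA
>neg71
CQVRFAY
>neg72
TYQSMDCKFHGF
>neg73
DLILIGK
>neg74
CCRVTTTYTLPT
>neg75
EFTEQQW
>neg76
VGENRQA
>neg77
HVTVPCM
>neg78
TRVHIEP
>neg79
TQEWYMF
>neg80
AANCHRYQNRAS
>neg81
KIWLCDGRMLPC
>neg82
SSPDPNM
>neg83
LYGMTYT
>neg84
WMEPFITTVDIM
>neg85
HQHEWRWAYCKH
>neg86
TDYILAN
>neg87
QEWNVWKDIKQR
>neg88
ACHIYQIPFMED
>neg89
NMQKAWCPFMQH
>neg90
DACWPRNGYPQN
>neg91
TNIGLQR
>neg92
SGKMIAV
>neg93
MYELDYVFQMQQ
>neg94
MYSTLCW
>neg95
PCTWEGHCWLRI
>neg96
VMITALRNECCA
>neg97
TGTKCQMHIDDY
>neg98
AWAHTLK
>neg99
NCETVKC
>neg100
DHYWAENVAYFD
>neg101
EKSDFKG
>neg102
IEKPTNHYNWTR
>neg103
TGEVAKDCLFDT
>neg104
IAIRLKTTIHRS
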