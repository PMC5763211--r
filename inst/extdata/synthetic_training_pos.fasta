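>pos1
CFFHSYW
>pos2
LCAYWVSWVKRW
>pos3
IWYEFHIIWHCE
>pos4
SWRPWCEWGMFW
>pos5
WDKWGDW
>pos6
FWYAWCRFKRNN
>pos7
RKFHKQW
>pos8
DGTMQGE
>pos9
QEMNFHSVWRNY
>pos10
CFYQFWFMWYWY
>pos11
YYQGGLHYIMSR
>pos12
FFRWEEW
>pos13
WKWFHNQWHYHA
>pos14
WHITDTELYTCF
>pos15
YWFWMFWASWVT
>pos16
LCFYFKWSWTTN
>pos17
FCKYVYCEYSHY
>pos18
FGWSIWYAFYLW
>pos19
WIEWAMDWWFVC
>pos20
CFNEAHGYFTCD
>pos21
RCFHLDW
>pos22
DWWWFSW
>pos23
PCFHITWANMNC
>pos24
QAWDWWMLDFMI
>pos25
FHWEWET
>pos26
WTLWMFQ
>pos27
WLAITFHCLWKT
>pos28
WLNEDVFLWIHW
>pos29
EWKWWWW
>pos30
WECLFHWGWFMI
>pos31
WALIGFHEWWWY
>pos32
YWHKWYF
>pos33
ICIYNPW
>pos34
FVYSNHWWKKYQ
>pos35
YTRPYFF
>pos36
PYWWEFHNTWWW
>pos37
WYRWNWW
>pos38
YLAAHQF
>pos39
ASLTFWHWNRWK
>pos40
IEWYLFWIGWYQ
>pos41
FTFHAYWFYTIK
>pos42
CVQKLYWLFSEF
>pos43
RTHIWSAWIVEW
>pos44
QTMYVIWQKCEH
>pos45
YWKSWFF
>pos46
WVKWPYN
>pos47
HMGCAEWLFPNV
>pos48
FHEHWSC
>pos49
YWLLWYW
>pos50
GWDYQWE
>pos51
FHDWWPY
>pos52
PWHNWFYMWEYK
>pos53
RNFHCAW
>pos54
WYWWDPWNEHWC
>pos55
IYKRFHPWTCHC
>pos56
WCVWWYL
>pos57
PYLWQKWNSCYY
>pos58
EGFHIYWGWTCF
>pos59
RRAMYYS
>pos60
YWYTWYH
>pos61
WFFSLKWFWSKW
>pos62
NSPPGPW
>pos63
EFHLCWHMTWYF
>pos64
SLFEWMCWVDVW
>pos65
LFHFVWG
>pos66
FSFVWFFYDLWA
>pos67
YFHIKWN
>pos68
QYWHVWI
>pos69
KWFHGKW
>pos70
WLAWFPE
>pos71
QQWCKFHYPWKF
>pos72
PNWHNIGSVNDC
>pos73
WISWEQEKDISK
>pos74
HWRQWLMFWDKF
>pos75
QYFWFGWVWASK
>pos76
WWDWHFHWFWDP
>pos77
HWYRWCEVWSHL
>pos78
GFHNIWSKFPCA
>pos79
WVWNMFAIMYVM
>pos80
FRIKNLWTFWSC
>pos81
RRFHRSW
>pos82
YWLRWED
>pos83
YRWSQWF
>pos84
KWFWQSYMDPDS
>pos85
WYEQVELWWTNW
>pos86
HEEKRRICGMYV
>pos87
FHWEWRF
>pos88
WMWWWFQWWGMY
>pos89
FWEYFPFWWEWW
>pos90
QFYMWQDWYKWK
>pos91
FHHEWYG
>pos92
RWGIGHCSLAFY
>pos93
FEESDPF
>pos94
WYGWCGGWVNVE
>pos95
WGMWNFF
>pos96
FHIFKSY
>pos97
KYTWCWT
>pos98
FFHHCWFYWCWE
>pos99
MWPYEWFHHNWG
>pos100
SIFEFQY
>pos101
WLMWPLAWIYPI
>pos102
YWENWSG
>pos103
DFHFNWT
>pos104
YRWYWKTWYTRP
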