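>synthetic_hre_01
ATACGCACACGTGCGGCCACCAGGGTCACCGAC
>synthetic_hre_02
TTAGGCACACGTGCGGTCACGAGGGTCACTGCC
>synthetic_hre_03
TTACGCACACGTGCGGGCGGCGGGGTCACTGAC
>synthetic_hre_04
TTACACACACGTGCGGTCACCAGGGTCATTGAC
>synthetic_hre_05
TTAAGCAAACGTGCCGCCACCAAGGTCACTGAC
>synthetic_hre_06
TTACACACACGTGCGGACACCAGGGTCACTGAC
>synthetic_hre_07
TTACGCGCACGTGTGGCCACGAGGGTCACTGAC
>synthetic_hre_08
TTACACACGCGTGCGTCCACCAGGGTCACTGAC
>synthetic_hre_09
TTACGCATGCGTGTGGCCACCAGGGTCACTGAC
>synthetic_hre_10
TTACGCACGCGTGCGGCCATCAGGGTCACAGAC
>synthetic_hre_11
TTAAGCACGCGTGCGGCCAACAGGGTCACCGAC
>synthetic_hre_12
TTACGCAGGCGTGCGGCCACCAGGGTCACTGGC
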