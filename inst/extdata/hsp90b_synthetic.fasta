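>HSP90B_SYNTHETIC synthetic 724-aa stand-in bait sequence (S226/S255/S261/K607 placed; not the real HSP90AB1 sequence)
TFALEVTRHEFQYVRDKEFPFYCIDALMRIEEVPFECVDTVGGCYDCGLIFATHEPLKNY
KMDSFQFCVTVFQIIEEHLVPWSTNKMSIGAPQFKSMLLAWTQQRGRMFSTTVCGGGYRC
LNKACCMQCCLFLTTFDQQAFDPMYTYEYMTKTPTYATACISDFPNAWFRGSLHKKDVRR
YSAGMKYPFMRCGAQSTMVCLEYRHTFYVKMGLKWKMWELTNGRKSVHQNWLFCDCQSEG
YYMAQAEPGNHNFVSPCDARSMKLHWVNLKWRQDYLCTVWQTLFPVWWLSCEHAQYWNWG
NLHWCGKMGFQLRAKLTNAMEDGFLYCEYKQQDVLAIYFGQEKISNLQMCSQRTGWLPGA
MPLPRTRIEGLYSNSWDHDLLHWPLQMPDLWCHYMMAGLKNPVRAMIPQCGPDPSWSPPI
PGGIFKLMAREHMLIDPYSIDKSMPHVHFYVHTDSIWVLRNDYSLCIAPHMMPFCRFQFT
VTVHPCNDYIYQAQVCFLNDVVVRAIWIYWCYWMRVILCETNYWHKWMMNTCYHTEPWAT
ECIDPCEKMLQAAQYMKWFCKDNCSVTYIIWRGDAREKAMGYQKGNTMKVMWAMTTIMVA
GCQFAVKRHQLDHFGFVKDDKPHLTCYTNGWLSALHCEYIRQTFTTSYGDQKNKQDEDHA
FEINNNRKDDKHNPTRRYDPWCFKVAEVFDLHQLLKHGYIFWYMTHLNEYDASFWTMAAV
DFHG
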