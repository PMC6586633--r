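>ATF3_SYNTHETIC synthetic stand-in sequence
MWHVHAFSFIHRNIILTDHSRETLDSAVGPQRWYVVMVESGHIVYRALSSDVGQLK
>ATF4_SYNTHETIC synthetic stand-in sequence
MYGFVTIQGFTRGFDILHNWDMAHRGLTDSVPAEFKMIMIFMVWLMFRSEQDLVTGSPRQIYYNEETRAVDSTLNPEGK
>ATF6_SYNTHETIC synthetic stand-in sequence
MLLVHTWYYFQRIQSYVMMFYMRAEPQPLSPASSSYSVSSPRSFDNTQDDLGRELDSVPGTAQKNWMVAGTFETTGRSGDLTNVFAK
>CHOP_SYNTHETIC synthetic stand-in sequence
MWSWVVWYEASRQDQFGGTQATFVSRELTSDFGAVQRMIDADYSAAIVYIRSDPLVTGEAK
>GADD34_SYNTHETIC synthetic stand-in sequence
MEFVDVEFGDMRQDGYMLDMAQNEIQRAPLSPSLLIRLSEQEIDLSVWVQSRTGELDSVPQAKNMLDWDQITMRNLDSFVGTEPR
>IRE1_SYNTHETIC synthetic stand-in sequence
MFMHSGMGYNYRWSVIYFMDRAVGTDLSSFLKDEHEYLVYLAEHRELDPSVTGYRGMQIDWHVGIISMSRSGIVDTLSAK
>PERK_SYNTHETIC synthetic stand-in sequence
MSHAMDGEAMYRTWYFHVNEIFHVGIRGGFGVVFEAKHIATYDSHGGSDRYLTDFEPIQCLGRWHNHVTLWDRTLDSEYNPVSR
>XBP1_SYNTHETIC synthetic stand-in sequence
MWTQTDAIMGDRFIHLHYFMLDIRSEVLDPTGAQKLTHEDSGENARGLDTESVPNAR
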