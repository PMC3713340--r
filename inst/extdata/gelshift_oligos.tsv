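name	target	sequence
YUCCA1cS	YUCCA1c	AAAAAATTACAAATAAATGACTTGACTAATGTTGTTATTAATCTCCACA
YUCCA1cA	YUCCA1c	TGTGGAGATTAATAACAACATTAGTCAAGTCATTTATTTGTAATTTTTT
IPTS	IPT	TTTTTTTTTGGTTTTAAGTTTGACAAGTCAGGTCTAATTTGACATCCTT
IPTA	IPT	AGGATGTCAAATTAGACCTGACTTGTCAAACTTAAAACCAAAAAAAAA
PIN1Fw	StPIN1	GTCTGTGTATGATTTTGACCTACATACAATCTGTCAACTAATGTGTATGA
PIN1Rv	StPIN1	TCATACACATTAGTTGACAGATTGTATGTAGGTCAAAATCATACACAGAC
PIN2Fw	StPIN2	AAATGTGAAAGTCACTATGTCAATCATTATTT
PIN2Rv	StPIN2	AAATAATGATTGACATAGTGACTTTCACATTT
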