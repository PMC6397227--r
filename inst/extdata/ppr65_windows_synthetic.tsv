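id	kind	ed_pct	read_cov	window
ccmFCeU103PS	native	NA	NA	GAAUGCUAAUCGAUAGCGGCAAGUAGAGCUCUUCCAUAU
OT1	offtarget	9.4	1520	GAUUGCUAAUCGAUAGCGGUAAGUGGAGCUCUUCCAUAU
OT2	offtarget	8.1	880	GAAUGCUAAUCGAUAGCGACAGGUGGAGCUCUUCCAUAU
OT3	offtarget	6.3	2210	GAAUGCUAAUCGAUAGCUGCGAGUGGAGCUCUUCCAUAU
OT4	offtarget	5.2	640	GAAUGCUAAUCGAUAGCGUCAAGCGGAGCUCUUCCAUAU
OT5	offtarget	3.7	430	GAAUGCUAAUCGAUAGCGGCCAGUGGGGCUCUUCCAUAU
OT6	offtarget	2.6	1900	GAAUGCUAAUCGAUAGCAGCAUGUGGAACUCUUCCAUAU
OT7	offtarget	1.8	350	GAAUGCUAAUCGAUAGCGGCAAAUGGAGCUAUUCCAUAU
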