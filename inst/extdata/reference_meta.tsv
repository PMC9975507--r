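line_id	alias	donor_age	sex	youngest_passage	condition	control_group
Young 1	AG07095	2	M	6	young	TRUE
Young 2	GM00969	2	F	13	young	TRUE
Young 3	GM05565	3	M	3	young	TRUE
Young 4	GM00498	3	M	10	young	TRUE
Young 5	GM00038	9	F	11	young	TRUE
Midage 1	own-lab	34	M	5	midage	FALSE
Midage 2	GM01653	37	M	14	midage	FALSE
Midage 3	own-lab	48	F	15	midage	FALSE
Old 1	GM09918	78	M	15	old	FALSE
Old 2	GM03525	80	F	9	old	FALSE
Old 3	GM01706	82	F	5	old	FALSE
Old 4	AG09602	92	F	9	old	FALSE
Old 5	AG04059	96	M	7	old	FALSE
Old 6	GM00731	96	M	13	old	FALSE
Repl Y1	NA	NA	NA	NA	replicative	FALSE
Repl Y2	NA	NA	NA	NA	replicative	FALSE
Repl M1	NA	NA	NA	NA	replicative	FALSE
Repl M2	NA	NA	NA	NA	replicative	FALSE
Repl O1	NA	NA	NA	NA	replicative	FALSE
Repl O2	NA	NA	NA	NA	replicative	FALSE
Young 1 prog	AG07095+progerin	2	M	6	artificial	FALSE
Young 4 prog	GM00498+progerin	3	M	10	artificial	FALSE
Young 5 prog	GM00038+progerin	9	F	11	artificial	FALSE
HGPS 1	HGADFN003	2	M	13	HGPS	FALSE
HGPS 2	HGADFN188	2	F	16	HGPS	FALSE
WS 1	AG03141	30	F	14	WS	FALSE
WS 2	AG06300	37	M	5	WS	FALSE
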