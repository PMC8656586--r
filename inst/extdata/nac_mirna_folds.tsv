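mirna_id	case_id	signed_fold	is_estimate
miR-195	case-1	3.46	FALSE
miR-195	case-2	1.84	FALSE
miR-195	case-3	1.70	FALSE
miR-195	case-4	1.33	FALSE
miR-195	case-5	4.50	FALSE
miR-26b	case-1	3.39	FALSE
miR-26b	case-2	1.54	FALSE
miR-26b	case-3	1.92	FALSE
miR-26b	case-4	1.79	FALSE
miR-26b	case-5	15.7	FALSE
let-7c	case-1	1.71	FALSE
let-7c	case-2	2.76	FALSE
let-7c	case-3	1.99	FALSE
let-7c	case-4	1.15	FALSE
let-7c	case-5	1.94	FALSE
miR-10a	case-1	-2.33	FALSE
miR-10a	case-2	-1.42	FALSE
miR-10a	case-3	-14.4	FALSE
miR-10a	case-4	-1.27	FALSE
miR-10a	case-5	-1.36	FALSE
miR-26a	case-1	1.72	FALSE
miR-26a	case-2	1.18	FALSE
miR-26a	case-3	2.83	FALSE
miR-26a	case-4	1.54	FALSE
miR-26a	case-5	2.69	FALSE
miR-330	case-1	1.70	FALSE
miR-330	case-2	1.32	FALSE
miR-330	case-3	1.11	FALSE
miR-330	case-4	1.82	FALSE
miR-330	case-5	30	TRUE
miR-335	case-1	3.15	FALSE
miR-335	case-2	4.94	FALSE
miR-335	case-3	1.16	FALSE
miR-335	case-4	1.55	FALSE
miR-335	case-5	120	TRUE
miR-362	case-1	1.68	FALSE
miR-362	case-2	1.03	FALSE
miR-362	case-3	1.27	FALSE
miR-362	case-4	2.85	FALSE
miR-362	case-5	100	TRUE
miR-483-5p	case-1	7020	FALSE
miR-483-5p	case-2	3.34	FALSE
miR-483-5p	case-3	1.13	FALSE
miR-483-5p	case-4	2.27	FALSE
miR-483-5p	case-5	19.9	FALSE
miR-885-5p	case-1	870	TRUE
miR-885-5p	case-2	1.14	FALSE
miR-885-5p	case-3	42.0	FALSE
miR-885-5p	case-4	2.69	FALSE
miR-885-5p	case-5	20	TRUE
miR-625	case-1	27.8	FALSE
miR-625	case-2	1.24	FALSE
miR-625	case-3	1.10	FALSE
miR-625	case-4	4.04	FALSE
miR-625	case-5	10	TRUE
miR-365	case-1	-1.18	FALSE
miR-365	case-2	-1.47	FALSE
miR-365	case-3	-4.03	FALSE
miR-365	case-4	-1.19	FALSE
miR-365	case-5	-1.66	FALSE
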