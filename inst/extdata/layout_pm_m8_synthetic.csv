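plate,well,compound,category,series_id,conc_rank
PM-M8,A01,Oxytocin,hormone,,
PM-M8,A02,Vasopressin,hormone,,
PM-M8,A03,Somatostatin,hormone,,
PM-M8,A04,Glucagon,hormone,,
PM-M8,A05,Growth Hormone,hormone,,
PM-M8,A06,Parathyroid Hormone,hormone,,
PM-M8,A07,Epinephrine,hormone,,
PM-M8,A08,Norepinephrine,hormone,,
PM-M8,A09,Substrate PM-M8-A09,hormone,,
PM-M8,A10,Substrate PM-M8-A10,hormone,,
PM-M8,A11,Substrate PM-M8-A11,hormone,,
PM-M8,A12,Substrate PM-M8-A12,hormone,,
PM-M8,B01,Substrate PM-M8-B01,hormone,,
PM-M8,B02,Substrate PM-M8-B02,hormone,,
PM-M8,B03,Substrate PM-M8-B03,hormone,,
PM-M8,B04,Substrate PM-M8-B04,hormone,,
PM-M8,B05,Substrate PM-M8-B05,hormone,,
PM-M8,B06,Substrate PM-M8-B06,hormone,,
PM-M8,B07,Substrate PM-M8-B07,hormone,,
PM-M8,B08,Substrate PM-M8-B08,hormone,,
PM-M8,B09,Substrate PM-M8-B09,hormone,,
PM-M8,B10,Substrate PM-M8-B10,hormone,,
PM-M8,B11,Substrate PM-M8-B11,hormone,,
PM-M8,B12,Substrate PM-M8-B12,hormone,,
PM-M8,C01,Substrate PM-M8-C01,hormone,,
PM-M8,C02,Substrate PM-M8-C02,hormone,,
PM-M8,C03,Substrate PM-M8-C03,hormone,,
PM-M8,C04,Substrate PM-M8-C04,hormone,,
PM-M8,C05,Substrate PM-M8-C05,hormone,,
PM-M8,C06,Substrate PM-M8-C06,hormone,,
PM-M8,C07,Substrate PM-M8-C07,hormone,,
PM-M8,C08,"Calcitriol (1a,25-dihydroxyvitamin D3)",hormone,,
PM-M8,C09,Substrate PM-M8-C09,hormone,,
PM-M8,C10,Substrate PM-M8-C10,hormone,,
PM-M8,C11,Substrate PM-M8-C11,hormone,,
PM-M8,C12,Substrate PM-M8-C12,hormone,,
PM-M8,D01,Substrate PM-M8-D01,hormone,,
PM-M8,D02,Substrate PM-M8-D02,hormone,,
PM-M8,D03,Substrate PM-M8-D03,hormone,,
PM-M8,D04,Substrate PM-M8-D04,hormone,,
PM-M8,D05,Substrate PM-M8-D05,hormone,,
PM-M8,D06,Luteinizing Hormone (LH),hormone,,
PM-M8,D07,Substrate PM-M8-D07,hormone,,
PM-M8,D08,Substrate PM-M8-D08,hormone,,
PM-M8,D09,Substrate PM-M8-D09,hormone,,
PM-M8,D10,Substrate PM-M8-D10,hormone,,
PM-M8,D11,Luteinizing Hormone Releasing Hormone (LH-RH),hormone,,
PM-M8,D12,Substrate PM-M8-D12,hormone,,
PM-M8,E01,Substrate PM-M8-E01,hormone,,
PM-M8,E02,Substrate PM-M8-E02,hormone,,
PM-M8,E03,Substrate PM-M8-E03,hormone,,
PM-M8,E04,Substrate PM-M8-E04,hormone,,
PM-M8,E05,Substrate PM-M8-E05,hormone,,
PM-M8,E06,Chorionic Gonadotropin Human (HCG),hormone,,
PM-M8,E07,Substrate PM-M8-E07,hormone,,
PM-M8,E08,Substrate PM-M8-E08,hormone,,
PM-M8,E09,Adrenocorticotrophic Hormone Human (ACTH),hormone,,
PM-M8,E10,Substrate PM-M8-E10,hormone,,
PM-M8,E11,Substrate PM-M8-E11,hormone,,
PM-M8,E12,Substrate PM-M8-E12,hormone,,
PM-M8,F01,Substrate PM-M8-F01,hormone,,
PM-M8,F02,Substrate PM-M8-F02,hormone,,
PM-M8,F03,Substrate PM-M8-F03,hormone,,
PM-M8,F04,Substrate PM-M8-F04,hormone,,
PM-M8,F05,Substrate PM-M8-F05,hormone,,
PM-M8,F06,Substrate PM-M8-F06,hormone,,
PM-M8,F07,Substrate PM-M8-F07,hormone,,
PM-M8,F08,Substrate PM-M8-F08,hormone,,
PM-M8,F09,Substrate PM-M8-F09,hormone,,
PM-M8,F10,Substrate PM-M8-F10,hormone,,
PM-M8,F11,Substrate PM-M8-F11,hormone,,
PM-M8,F12,Thyrotropin Releasing Hormone Acetate Salt (TRH),hormone,,
PM-M8,G01,Substrate PM-M8-G01,hormone,,
PM-M8,G02,Substrate PM-M8-G02,hormone,,
PM-M8,G03,Substrate PM-M8-G03,hormone,,
PM-M8,G04,Substrate PM-M8-G04,hormone,,
PM-M8,G05,Substrate PM-M8-G05,hormone,,
PM-M8,G06,Substrate PM-M8-G06,hormone,,
PM-M8,G07,Substrate PM-M8-G07,hormone,,
PM-M8,G08,Substrate PM-M8-G08,hormone,,
PM-M8,G09,Substrate PM-M8-G09,hormone,,
PM-M8,G10,TNF-alpha,metabolic_effector,,
PM-M8,G11,Substrate PM-M8-G11,hormone,,
PM-M8,G12,Substrate PM-M8-G12,hormone,,
PM-M8,H01,Substrate PM-M8-H01,hormone,,
PM-M8,H02,Substrate PM-M8-H02,hormone,,
PM-M8,H03,Substrate PM-M8-H03,hormone,,
PM-M8,H04,Substrate PM-M8-H04,hormone,,
PM-M8,H05,Substrate PM-M8-H05,hormone,,
PM-M8,H06,Substrate PM-M8-H06,hormone,,
PM-M8,H07,Substrate PM-M8-H07,hormone,,
PM-M8,H08,Substrate PM-M8-H08,hormone,,
PM-M8,H09,Substrate PM-M8-H09,hormone,,
PM-M8,H10,Substrate PM-M8-H10,hormone,,
PM-M8,H11,Substrate PM-M8-H11,hormone,,
PM-M8,H12,Substrate PM-M8-H12,hormone,,
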