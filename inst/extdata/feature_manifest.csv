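"feature_index","feature_name","family"
1,"hist_mean","histogram"
2,"hist_variance","histogram"
3,"hist_skewness","histogram"
4,"hist_kurtosis","histogram"
5,"hist_median","histogram"
6,"hist_min","histogram"
7,"hist_max","histogram"
8,"hist_range","histogram"
9,"hist_p10","histogram"
10,"hist_p90","histogram"
11,"hist_mad","histogram"
12,"hist_energy","histogram"
13,"hist_entropy","histogram"
14,"glcm2d_energy_0","glcm2d"
15,"glcm2d_contrast_0","glcm2d"
16,"glcm2d_correlation_0","glcm2d"
17,"glcm2d_variance_0","glcm2d"
18,"glcm2d_idm_0","glcm2d"
19,"glcm2d_sum_average_0","glcm2d"
20,"glcm2d_sum_variance_0","glcm2d"
21,"glcm2d_sum_entropy_0","glcm2d"
22,"glcm2d_entropy_0","glcm2d"
23,"glcm2d_diff_variance_0","glcm2d"
24,"glcm2d_diff_entropy_0","glcm2d"
25,"glcm2d_imc1_0","glcm2d"
26,"glcm2d_imc2_0","glcm2d"
27,"glcm2d_autocorrelation_0","glcm2d"
28,"glcm2d_max_prob_0","glcm2d"
29,"glcm2d_energy_45","glcm2d"
30,"glcm2d_contrast_45","glcm2d"
31,"glcm2d_correlation_45","glcm2d"
32,"glcm2d_variance_45","glcm2d"
33,"glcm2d_idm_45","glcm2d"
34,"glcm2d_sum_average_45","glcm2d"
35,"glcm2d_sum_variance_45","glcm2d"
36,"glcm2d_sum_entropy_45","glcm2d"
37,"glcm2d_entropy_45","glcm2d"
38,"glcm2d_diff_variance_45","glcm2d"
39,"glcm2d_diff_entropy_45","glcm2d"
40,"glcm2d_imc1_45","glcm2d"
41,"glcm2d_imc2_45","glcm2d"
42,"glcm2d_autocorrelation_45","glcm2d"
43,"glcm2d_max_prob_45","glcm2d"
44,"glcm2d_energy_90","glcm2d"
45,"glcm2d_contrast_90","glcm2d"
46,"glcm2d_correlation_90","glcm2d"
47,"glcm2d_variance_90","glcm2d"
48,"glcm2d_idm_90","glcm2d"
49,"glcm2d_sum_average_90","glcm2d"
50,"glcm2d_sum_variance_90","glcm2d"
51,"glcm2d_sum_entropy_90","glcm2d"
52,"glcm2d_entropy_90","glcm2d"
53,"glcm2d_diff_variance_90","glcm2d"
54,"glcm2d_diff_entropy_90","glcm2d"
55,"glcm2d_imc1_90","glcm2d"
56,"glcm2d_imc2_90","glcm2d"
57,"glcm2d_autocorrelation_90","glcm2d"
58,"glcm2d_max_prob_90","glcm2d"
59,"glcm2d_energy_135","glcm2d"
60,"glcm2d_contrast_135","glcm2d"
61,"glcm2d_correlation_135","glcm2d"
62,"glcm2d_variance_135","glcm2d"
63,"glcm2d_idm_135","glcm2d"
64,"glcm2d_sum_average_135","glcm2d"
65,"glcm2d_sum_variance_135","glcm2d"
66,"glcm2d_sum_entropy_135","glcm2d"
67,"glcm2d_entropy_135","glcm2d"
68,"glcm2d_diff_variance_135","glcm2d"
69,"glcm2d_diff_entropy_135","glcm2d"
70,"glcm2d_imc1_135","glcm2d"
71,"glcm2d_imc2_135","glcm2d"
72,"glcm2d_autocorrelation_135","glcm2d"
73,"glcm2d_max_prob_135","glcm2d"
74,"gldm2d_contrast_0","gldm2d"
75,"gldm2d_asm_0","gldm2d"
76,"gldm2d_entropy_0","gldm2d"
77,"gldm2d_mean_0","gldm2d"
78,"gldm2d_idm_0","gldm2d"
79,"gldm2d_contrast_45","gldm2d"
80,"gldm2d_asm_45","gldm2d"
81,"gldm2d_entropy_45","gldm2d"
82,"gldm2d_mean_45","gldm2d"
83,"gldm2d_idm_45","gldm2d"
84,"gldm2d_contrast_90","gldm2d"
85,"gldm2d_asm_90","gldm2d"
86,"gldm2d_entropy_90","gldm2d"
87,"gldm2d_mean_90","gldm2d"
88,"gldm2d_idm_90","gldm2d"
89,"gldm2d_contrast_135","gldm2d"
90,"gldm2d_asm_135","gldm2d"
91,"gldm2d_entropy_135","gldm2d"
92,"gldm2d_mean_135","gldm2d"
93,"gldm2d_idm_135","gldm2d"
94,"glcm3d_energy_mean","glcm3d"
95,"glcm3d_contrast_mean","glcm3d"
96,"glcm3d_correlation_mean","glcm3d"
97,"glcm3d_variance_mean","glcm3d"
98,"glcm3d_idm_mean","glcm3d"
99,"glcm3d_sum_average_mean","glcm3d"
100,"glcm3d_sum_variance_mean","glcm3d"
101,"glcm3d_sum_entropy_mean","glcm3d"
102,"glcm3d_entropy_mean","glcm3d"
103,"glcm3d_diff_variance_mean","glcm3d"
104,"glcm3d_diff_entropy_mean","glcm3d"
105,"glcm3d_imc1_mean","glcm3d"
106,"glcm3d_imc2_mean","glcm3d"
107,"glcm3d_autocorrelation_mean","glcm3d"
108,"glcm3d_max_prob_mean","glcm3d"
109,"glcm3d_energy_range","glcm3d"
110,"glcm3d_contrast_range","glcm3d"
111,"glcm3d_correlation_range","glcm3d"
112,"glcm3d_variance_range","glcm3d"
113,"glcm3d_idm_range","glcm3d"
114,"glcm3d_sum_average_range","glcm3d"
115,"glcm3d_sum_variance_range","glcm3d"
116,"glcm3d_sum_entropy_range","glcm3d"
117,"glcm3d_entropy_range","glcm3d"
118,"glcm3d_diff_variance_range","glcm3d"
119,"glcm3d_diff_entropy_range","glcm3d"
120,"glcm3d_imc1_range","glcm3d"
121,"glcm3d_imc2_range","glcm3d"
122,"glcm3d_autocorrelation_range","glcm3d"
123,"glcm3d_max_prob_range","glcm3d"
124,"glcm3d_energy_min","glcm3d"
125,"glcm3d_contrast_min","glcm3d"
126,"glcm3d_correlation_min","glcm3d"
127,"glcm3d_variance_min","glcm3d"
128,"glcm3d_idm_min","glcm3d"
129,"glcm3d_sum_average_min","glcm3d"
130,"glcm3d_sum_variance_min","glcm3d"
131,"glcm3d_sum_entropy_min","glcm3d"
132,"glcm3d_entropy_min","glcm3d"
133,"glcm3d_diff_variance_min","glcm3d"
134,"glcm3d_diff_entropy_min","glcm3d"
135,"glcm3d_imc1_min","glcm3d"
136,"glcm3d_imc2_min","glcm3d"
137,"glcm3d_autocorrelation_min","glcm3d"
138,"glcm3d_max_prob_min","glcm3d"
139,"glcm3d_energy_max","glcm3d"
140,"glcm3d_contrast_max","glcm3d"
141,"glcm3d_correlation_max","glcm3d"
142,"glcm3d_variance_max","glcm3d"
143,"glcm3d_idm_max","glcm3d"
144,"glcm3d_sum_average_max","glcm3d"
145,"glcm3d_sum_variance_max","glcm3d"
146,"glcm3d_sum_entropy_max","glcm3d"
147,"glcm3d_entropy_max","glcm3d"
148,"glcm3d_diff_variance_max","glcm3d"
149,"glcm3d_diff_entropy_max","glcm3d"
150,"glcm3d_imc1_max","glcm3d"
151,"glcm3d_imc2_max","glcm3d"
152,"glcm3d_autocorrelation_max","glcm3d"
153,"glcm3d_max_prob_max","glcm3d"
154,"gldm3d_contrast_mean","gldm3d"
155,"gldm3d_asm_mean","gldm3d"
156,"gldm3d_entropy_mean","gldm3d"
157,"gldm3d_mean_mean","gldm3d"
158,"gldm3d_idm_mean","gldm3d"
159,"gldm3d_contrast_range","gldm3d"
160,"gldm3d_asm_range","gldm3d"
161,"gldm3d_entropy_range","gldm3d"
162,"gldm3d_mean_range","gldm3d"
163,"gldm3d_idm_range","gldm3d"
164,"gldm3d_contrast_min","gldm3d"
165,"gldm3d_asm_min","gldm3d"
166,"gldm3d_entropy_min","gldm3d"
167,"gldm3d_mean_min","gldm3d"
168,"gldm3d_idm_min","gldm3d"
169,"gldm3d_contrast_max","gldm3d"
170,"gldm3d_asm_max","gldm3d"
171,"gldm3d_entropy_max","gldm3d"
172,"gldm3d_mean_max","gldm3d"
173,"gldm3d_idm_max","gldm3d"
174,"glrlm2d_sre_mean","glrlm2d"
175,"glrlm2d_lre_mean","glrlm2d"
176,"glrlm2d_gln_mean","glrlm2d"
177,"glrlm2d_rln_mean","glrlm2d"
178,"glrlm2d_rp_mean","glrlm2d"
179,"glrlm2d_lgre_mean","glrlm2d"
180,"glrlm2d_hgre_mean","glrlm2d"
181,"glrlm2d_srlge_mean","glrlm2d"
182,"glrlm2d_srhge_mean","glrlm2d"
183,"glrlm2d_lrlge_mean","glrlm2d"
184,"glrlm2d_lrhge_mean","glrlm2d"
185,"glrlm2d_sre_min","glrlm2d"
186,"glrlm2d_lre_min","glrlm2d"
187,"glrlm2d_gln_min","glrlm2d"
188,"glrlm2d_rln_min","glrlm2d"
189,"glrlm2d_rp_min","glrlm2d"
190,"glrlm2d_lgre_min","glrlm2d"
191,"glrlm2d_hgre_min","glrlm2d"
192,"glrlm2d_srlge_min","glrlm2d"
193,"glrlm2d_srhge_min","glrlm2d"
194,"glrlm2d_lrlge_min","glrlm2d"
195,"glrlm2d_lrhge_min","glrlm2d"
196,"glrlm2d_sre_max","glrlm2d"
197,"glrlm2d_lre_max","glrlm2d"
198,"glrlm2d_gln_max","glrlm2d"
199,"glrlm2d_rln_max","glrlm2d"
200,"glrlm2d_rp_max","glrlm2d"
201,"glrlm2d_lgre_max","glrlm2d"
202,"glrlm2d_hgre_max","glrlm2d"
203,"glrlm2d_srlge_max","glrlm2d"
204,"glrlm2d_srhge_max","glrlm2d"
205,"glrlm2d_lrlge_max","glrlm2d"
206,"glrlm2d_lrhge_max","glrlm2d"
207,"glrlm3d_sre_mean","glrlm3d"
208,"glrlm3d_lre_mean","glrlm3d"
209,"glrlm3d_gln_mean","glrlm3d"
210,"glrlm3d_rln_mean","glrlm3d"
211,"glrlm3d_rp_mean","glrlm3d"
212,"glrlm3d_lgre_mean","glrlm3d"
213,"glrlm3d_hgre_mean","glrlm3d"
214,"glrlm3d_srlge_mean","glrlm3d"
215,"glrlm3d_srhge_mean","glrlm3d"
216,"glrlm3d_lrlge_mean","glrlm3d"
217,"glrlm3d_lrhge_mean","glrlm3d"
218,"fft_mag_mean","fft"
219,"fft_mag_sd","fft"
220,"fft_mag_skewness","fft"
221,"fft_mag_kurtosis","fft"
222,"fft_mag_energy","fft"
223,"fft_mag_entropy","fft"
224,"fft_mag_max","fft"
225,"fft_mag_rcentroid","fft"
226,"fft_mag_rspread","fft"
227,"fft_phase_mean","fft"
228,"fft_phase_sd","fft"
229,"fft_phase_skewness","fft"
230,"fft_phase_kurtosis","fft"
231,"fft_phase_energy","fft"
232,"fft_phase_entropy","fft"
233,"fft_phase_max","fft"
234,"fft_phase_rcentroid","fft"
235,"fft_phase_rspread","fft"
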