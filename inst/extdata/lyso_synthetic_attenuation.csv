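# Synthetic LYSO-like linear attenuation coefficients (1/mm).
# Computed analytically: Compton = electron density x integrated
# Klein-Nishina cross-section; photoelectric ~ E^-3 pinned at 511 keV;
# Rayleigh ~ E^-2, small. Not a measured compilation.
# Regenerate with: Rscript tools/make_attenuation_table.R
"energy_keV","mu_photo","mu_compton","mu_rayleigh"
50,29.888954144,0.102531199328758,0.4177936
53.3112159366019,24.6584042037528,0.10154491045199,0.367506153524819
56.8417148927799,20.3431975219419,0.100521700386838,0.323271521819885
60.606018737115,16.7831495500328,0.099461656030071,0.284361161894631
64.6196110390416,13.8461079441891,0.0983650203001892,0.250134221346962
68.8990007568314,11.4230469454264,0.0972321999296766,0.220026983544381
73.4617901432707,9.42402024044432,0.0960637718026673,0.193543583228811
78.3267471483448,7.774822069506,0.0948604875785193,0.170247839631414
83.5138826167405,6.41423263853554,0.0936232763539536,0.149756072589075
89.0445325977016,5.29174558252865,0.0923532451388845,0.131730783344203
94.9414461057971,4.3656931215711,0.0910516769539181,0.115875095950822
101.228878693588,3.60169931348547,0.0897200264007279,0.101927867737098
107.932692221079,2.97140398638313,0.0883599126101354,0.0896593882937593
115.080461232335,2.45140998229227,0.0869731095355654,0.0788675961508929
122.701586376815,2.0224146325512,0.085561533630291,0.0693747508319024
130.82741534196,1.6684932245126,0.0841272290231928,0.0610245054734568
139.491371794454,1.37650786116629,0.0826723503870613,0.0536793317975777
148.729092860539,1.13561976999102,0.0811991437724296,0.0472182550252333
158.578575710863,0.936886957479333,0.0797099257550232,0.0415348614255399
169.080333852811,0.772932273891129,0.0782070613124135,0.0365355456849664
180.277563773199,0.637669566486295,0.0766929409015886,0.0321379692307692
192.216322616751,0.526077755785488,0.0751699572506037,0.0282697041172938
204.945717631223,0.434014448356528,0.073640482401368,0.0248670401399911
218.518108158399,0.358062167256946,0.07210684554483,0.0218739355303562
232.989321001803,0.295401492061439,0.0705713121733307,0.0192410939497663
248.418880056988,0.243706399312231,0.0690360650376253,0.016925152580337
264.870251148938,0.201057918330961,0.0675031873392189,0.0148879679406778
282.41110308366,0.165872897214278,0.0659746485145172,0.0130959876639549
301.113585987739,0.136845234739613,0.0644522928791398,0.0115196978914673
321.054628080738,0.112897396653947,0.0629378313027476,0.0101331371803233
342.316252101152,0.0931404165844086,0.0614328359815501,0.00891346891929403
364.985912687456,0.0768408967667179,0.0599387382722824,0.00784060521054602
389.156856101974,0.0633937836273517,0.0584568294526973,0.00689687602259686
414.928503777229,0.0522999076233079,0.0569882641840656,0.0060667381654533
442.406861262379,0.0431474535971125,0.0555340663746144,0.00533651929476173
471.70495425186,0.0355966738091386,0.0540951370822526,0.00469419272872745
502.943293489716,0.0293672761805581,0.0526722640522623,0.00412917936904444
536.25037046192,0.0242280195865873,0.0512661324617374,0.00363217346347948
571.763185915564,0.0199881299674863,0.0498773364372184,0.00319498934042615
609.627813378881,0.0164902186152393,0.0485063909240175,0.00281042659115126
650,0.013604439756031,0.0471537435131605,0.00247215147928994
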