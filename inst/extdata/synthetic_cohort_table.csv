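ID,Lf_rest0_mm,PA_rest0_deg,MT_rest0_mm,Lf_rest60_mm,PA_rest60_deg,MT_rest60_mm,Lf_mvc60_mm,PA_mvc60_deg,MT_mvc60_mm,Fmax_N,Fiso400_N,G_curv,L0_mm,Wjoint_100_J,Notes
P01,83.9,13.6,19.8,137,11.9,28.3,96.4,10.8,18.1,6187,3444,3.49,133.5,104.8,synthetic
P02,80.3,13.6,18.9,111.7,10.9,21,111.1,13.4,25.7,4482,603,5.97,97.7,47.2,synthetic
P03,76.8,15.5,20.5,116.3,12.1,24.3,92.7,16.3,26,4958,2196,8.59,85.9,82.2,synthetic
P04,77.3,16.3,21.7,121.6,10.1,21.4,119.7,13.8,28.6,4094,1281,6.75,112,59.1,synthetic
P05,68.7,20.3,23.9,108.4,9.7,18.2,112.9,13.4,26.2,4718,1688,5.26,96,73.4,synthetic
P06,89.3,15.3,23.6,113,11,21.5,94.7,13.6,22.3,4166,1537,6.72,119,62.7,synthetic
P07,97.6,11,18.6,116.8,9.2,18.7,107.9,15.2,28.3,4656,2134,3.69,120.2,76.7,synthetic
P08,79.7,13.8,19,127.6,9.5,21.1,79.9,12.6,17.4,2633,1173,4.11,113.4,42.5,synthetic
P09,75.3,18.4,23.8,103.2,12.1,21.6,69.9,15.7,18.9,6755,3225,5.95,94.4,116.4,synthetic
P10,82.9,20.9,29.6,106.1,10.6,19.6,90.8,20,31,5798,2808,5.56,103.8,101.7,synthetic
P11,70.1,19.5,23.4,110.2,13.1,25,60,13.7,14.2,6116,3337,4.38,85.9,100.4,synthetic
P12,81.9,15.8,22.3,118,10,20.5,75.8,11.2,14.8,4923,2675,3.82,82,87.4,synthetic
P13,69,14.4,17.1,134.2,9.7,22.6,89.3,15.7,24.1,5313,3399,4.02,94.6,96.5,synthetic
P14,77.2,15.5,20.6,99.6,12.2,21,104.9,12.2,22.2,5030,3120,3,97.5,95.1,synthetic
P15,83.3,15.4,22.1,133.7,10.5,24.4,105.7,14.6,26.6,4948,2725,5.75,110.5,91,synthetic
P16,78.5,13.3,18.1,120.4,9.5,19.8,107.4,13.5,25,3472,1393,5.89,97.6,55.8,synthetic
P17,84.7,14.5,21.3,117.2,6.7,13.6,109.5,10,18.9,3594,1558,9,111.1,57.5,synthetic
P18,94.5,14.9,24.3,121.9,9.1,19.2,110.5,13.8,26.5,3945,1923,5.67,114,61.2,synthetic
P19,88.2,16.9,25.7,109.7,11.7,22.3,96.8,15.9,26.5,6093,3073,5.33,119.7,105.5,synthetic
P20,72.5,14.9,18.6,91,11.1,17.5,111.5,15.8,30.4,6412,3241,5.66,88.9,113.4,synthetic
P21,76.1,16.2,21.2,124,8.6,18.6,101.8,14.8,26.1,5085,1390,5.27,110.8,70.4,synthetic
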