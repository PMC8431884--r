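species,sample,N,AR,PA,MLG,Hprime,lambda,E5,Hexp,Ho
M. acuminata,population,76,73,33,70,4.214,0.984,0.948,0.290,0.045
M. acuminata,seeds,104,37,2,25,2.704,0.905,0.684,0.238,0.023
M. balbisiana,population,83,48,16,82,4.402,0.988,0.993,0.314,0.336
M. balbisiana,seeds,73,39,6,60,4.029,0.981,0.919,0.227,0.083
M. maclayi,population,57,242,27,55,3.994,0.981,0.981,0.897,0.723
M. maclayi,seeds,52,224,8,52,3.951,0.981,1.000,0.872,0.750
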