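mutation,group,paired_mutation,qf_key,modality,hr_mean,hr_sem,n,study,excluded
A414G,carrier,A414G,A414G,holter_min,31.0,0.7,2,Milano et al.,FALSE
A414G,carrier,A414G,A414G,holter_avg,60.5,3.9,2,Milano et al.,FALSE
A414G,carrier,A414G,A414G,holter_max,140.0,20.5,2,Milano et al.,FALSE
G480R,carrier,G480R,G480R,holter_min,31.7,3.0,7,Nof et al.,FALSE
G480R,carrier,G480R,G480R,holter_avg,48.9,4.3,7,Nof et al.,FALSE
G480R,carrier,G480R,G480R,holter_max,101.3,7.5,7,Nof et al.,FALSE
non_carrier,non_carrier,G480R,WT,holter_min,55.0,3.1,8,Nof et al.,FALSE
non_carrier,non_carrier,G480R,WT,holter_avg,73.5,3.7,8,Nof et al.,FALSE
non_carrier,non_carrier,G480R,WT,holter_max,125.8,5.5,8,Nof et al.,FALSE
Y481H,carrier,Y481H,Y481H,holter_min,27.5,0.4,2,Milano et al.,FALSE
Y481H,carrier,Y481H,Y481H,holter_avg,47.0,2.1,2,Milano et al.,FALSE
Y481H,carrier,Y481H,Y481H,holter_max,93.0,0.7,2,Milano et al.,FALSE
G482R,carrier,G482R,G482R_a,holter_min,30.5,4.0,6,Milano et al.,FALSE
G482R,carrier,G482R,G482R_a,holter_avg,54.0,6.3,6,Milano et al.,FALSE
G482R,carrier,G482R,G482R_a,holter_max,120.5,10.5,6,Milano et al.,FALSE
non_carrier,non_carrier,G482R,WT,holter_min,38,NA,1,Milano et al.,FALSE
non_carrier,non_carrier,G482R,WT,holter_avg,63,NA,1,Milano et al.,FALSE
non_carrier,non_carrier,G482R,WT,holter_max,103,NA,1,Milano et al.,FALSE
G482R,carrier,G482R,G482R_b,holter_min,25.0,2.2,3,Schweizer et al. (G482R),FALSE
G482R,carrier,G482R,G482R_b,holter_avg,41.0,4.2,3,Schweizer et al. (G482R),FALSE
G482R,carrier,G482R,G482R_b,holter_max,120.3,5.0,3,Schweizer et al. (G482R),FALSE
non_carrier,non_carrier,G482R,WT,holter_min,48,NA,1,Schweizer et al. (G482R),FALSE
non_carrier,non_carrier,G482R,WT,holter_avg,63,NA,1,Schweizer et al. (G482R),FALSE
non_carrier,non_carrier,G482R,WT,holter_max,155,NA,1,Schweizer et al. (G482R),FALSE
G482R,carrier,G482R,NA,holter_min,29.3,3.7,3,Brunet-Garcia et al.,FALSE
G482R,carrier,G482R,NA,holter_avg,55,4.2,2,Brunet-Garcia et al.,FALSE
G482R,carrier,G482R,NA,holter_max,159.0,4.2,2,Brunet-Garcia et al.,FALSE
A485V,carrier,A485V,A485V,holter_min,36.9,0.8,14,Laish-Farkash et al.,FALSE
A485V,carrier,A485V,A485V,holter_avg,58.1,1.5,14,Laish-Farkash et al.,FALSE
A485V,carrier,A485V,A485V,holter_max,116.9,7.0,14,Laish-Farkash et al.,FALSE
non_carrier,non_carrier,A485V,WT,holter_min,48.6,4.5,5,Laish-Farkash et al.,FALSE
non_carrier,non_carrier,A485V,WT,holter_avg,77.2,4.9,5,Laish-Farkash et al.,FALSE
non_carrier,non_carrier,A485V,WT,holter_max,140.4,13.0,5,Laish-Farkash et al.,FALSE
K530N,carrier,K530N,K530N,holter_min,37.8,2.3,6,Duhme et al.,FALSE
K530N,carrier,K530N,K530N,holter_avg,62.8,3.1,6,Duhme et al.,FALSE
K530N,carrier,K530N,K530N,holter_max,133.5,11.2,6,Duhme et al.,FALSE
R666Q,carrier,R666Q,R666Q,holter_min,45.0,0.7,2,Wang et al.,FALSE
R666Q,carrier,R666Q,R666Q,holter_avg,50.0,1.4,2,Wang et al.,FALSE
695X,carrier,695X,695X,holter_min,35.9,2.0,7,Schweizer et al. (695X),FALSE
695X,carrier,695X,695X,holter_avg,56.4,1.7,7,Schweizer et al. (695X),FALSE
695X,carrier,695X,695X,holter_max,131.4,6.1,7,Schweizer et al. (695X),FALSE
non_carrier,non_carrier,695X,WT,holter_min,47.2,2.2,6,Schweizer et al. (695X),FALSE
non_carrier,non_carrier,695X,WT,holter_avg,71.7,3.8,6,Schweizer et al. (695X),FALSE
non_carrier,non_carrier,695X,WT,holter_max,157.5,9.6,6,Schweizer et al. (695X),FALSE
R375C,carrier,R375C,R375C,resting,49.7,3.2,12,Alonso-Fernandez-Gatta et al.,FALSE
R375C,carrier,R375C,R375C,exercise_max,81.5,2.8,11,Alonso-Fernandez-Gatta et al.,TRUE
R378C,carrier,R378C,R378C,resting,47.0,6.5,3,Moller et al.,FALSE
G480R,carrier,G480R,G480R,exercise_max,149.8,6.3,6,Nof et al.,FALSE
non_carrier,non_carrier,G480R,WT,exercise_max,152.7,8.4,6,Nof et al.,FALSE
Y481H,carrier,Y481H,Y481H,resting,44.1,2.4,8,Vermeer et al.,FALSE
G482R,carrier,G482R,G482R_b,resting,39.7,2.6,3,Schweizer et al. (G482R),FALSE
non_carrier,non_carrier,G482R,WT,resting,64,NA,1,Schweizer et al. (G482R),FALSE
G482R,carrier,G482R,NA,resting,44.0,4.2,2,Brunet-Garcia et al.,FALSE
A485V,carrier,A485V,A485V,exercise_max,166.6,6.0,8,Laish-Farkash et al.,FALSE
non_carrier,non_carrier,A485V,WT,exercise_max,177.3,6.0,4,Laish-Farkash et al.,FALSE
K530N,carrier,K530N,K530N,resting,57.5,2.5,4,Duhme et al.,FALSE
R550C,carrier,R550C,R550C,resting,60.0,0.8,3,Campostrini et al.,FALSE
S672R,carrier,S672R,S672R,resting,52.2,1.4,15,Milanesi et al.,FALSE
non_carrier,non_carrier,S672R,WT,resting,73.2,1.6,12,Milanesi et al.,FALSE
695X,carrier,695X,695X,resting,45.9,1.5,8,Schweizer et al. (695X),FALSE
695X,carrier,695X,695X,exercise_max,160.3,4.4,7,Schweizer et al. (695X),FALSE
non_carrier,non_carrier,695X,WT,resting,66.5,3.4,6,Schweizer et al. (695X),FALSE
non_carrier,non_carrier,695X,WT,exercise_max,169.2,6.5,6,Schweizer et al. (695X),FALSE
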