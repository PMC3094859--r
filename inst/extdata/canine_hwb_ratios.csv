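group,dog,session,hwb_pct
epicardial,1,1,31.8
epicardial,2,1,19.4
epicardial,3,1,45.3
epicardial,4,1,49.2
epicardial,5,1,62.6
epicardial,6,1,56.4
epicardial,7,1,59.7
epicardial,8,1,57.8
epicardial,9,1,49.5
epicardial,1,2,29.4
epicardial,2,2,18.3
epicardial,3,2,NA
epicardial,4,2,47.6
epicardial,5,2,60.5
epicardial,6,2,53.6
epicardial,7,2,56.9
epicardial,8,2,NA
epicardial,9,2,45.1
epicardial,1,3,NA
epicardial,2,3,NA
epicardial,3,3,NA
epicardial,4,3,46.8
epicardial,5,3,NA
epicardial,6,3,NA
epicardial,7,3,55.0
epicardial,8,3,54.1
epicardial,9,3,42.9
epicardial,1,4,27.9
epicardial,2,4,17.4
epicardial,3,4,NA
epicardial,4,4,46.3
epicardial,5,4,59.2
epicardial,6,4,52.5
epicardial,7,4,54.2
epicardial,8,4,NA
epicardial,9,4,NA
epicardial,1,5,NA
epicardial,2,5,NA
epicardial,3,5,NA
epicardial,4,5,46.2
epicardial,5,5,57.2
epicardial,6,5,NA
epicardial,7,5,NA
epicardial,8,5,51.4
epicardial,9,5,41.0
epicardial,1,6,26.3
epicardial,2,6,17.1
epicardial,3,6,NA
epicardial,4,6,45.5
epicardial,5,6,56.4
epicardial,6,6,51.2
epicardial,7,6,52.5
epicardial,8,6,49.3
epicardial,9,6,39.4
endocardial,1,1,22.8
endocardial,2,1,42.9
endocardial,3,1,45.5
endocardial,4,1,44.0
endocardial,5,1,54.1
endocardial,6,1,62.5
endocardial,7,1,60.0
endocardial,8,1,49.2
endocardial,9,1,59.8
endocardial,10,1,57.6
endocardial,1,2,23.9
endocardial,2,2,40.8
endocardial,3,2,43.2
endocardial,4,2,42.3
endocardial,5,2,52.0
endocardial,6,2,60.3
endocardial,7,2,56.1
endocardial,8,2,47.6
endocardial,9,2,54.4
endocardial,10,2,54.8
endocardial,1,3,21.3
endocardial,2,3,39.0
endocardial,3,3,40.6
endocardial,4,3,40.9
endocardial,5,3,50.1
endocardial,6,3,59.5
endocardial,7,3,54.0
endocardial,8,3,44.7
endocardial,9,3,50.5
endocardial,10,3,52.5
endocardial,1,4,20.6
endocardial,2,4,37.9
endocardial,3,4,38.9
endocardial,4,4,NA
endocardial,5,4,48.5
endocardial,6,4,58.4
endocardial,7,4,52.3
endocardial,8,4,43.0
endocardial,9,4,47.2
endocardial,10,4,50.2
endocardial,1,5,19.9
endocardial,2,5,36.9
endocardial,3,5,37.5
endocardial,4,5,40.1
endocardial,5,5,47.7
endocardial,6,5,57.6
endocardial,7,5,51.4
endocardial,8,5,41.6
endocardial,9,5,44.5
endocardial,10,5,48.4
endocardial,1,6,19.1
endocardial,2,6,36.3
endocardial,3,6,36.8
endocardial,4,6,39.4
endocardial,5,6,46.7
endocardial,6,6,NA
endocardial,7,6,NA
endocardial,8,6,NA
endocardial,9,6,NA
endocardial,10,6,NA
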