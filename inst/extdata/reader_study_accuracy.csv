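reader_id,experience_years,group,mode,operating_point,solo_acc,ai_acc
R1,13,senior,birads,4a+,73.3,71.7
R1,13,senior,birads,4b+,80.0,83.3
R1,13,senior,birads,4c+,72.5,71.0
R1,13,senior,bm,bm,84.2,84.2
R2,2,junior,birads,4a+,64.1,71.7
R2,2,junior,birads,4b+,77.5,82.5
R2,2,junior,birads,4c+,73.3,78.3
R2,2,junior,bm,bm,70.8,77.5
R3,5,middle,birads,4a+,74.1,78.3
R3,5,middle,birads,4b+,71.6,85.8
R3,5,middle,birads,4c+,55.0,63.3
R3,5,middle,bm,bm,75.0,80.8
R4,3,middle,birads,4a+,55.8,58.3
R4,3,middle,birads,4b+,77.5,82.5
R4,3,middle,birads,4c+,70.0,80.0
R4,3,middle,bm,bm,79.1,82.5
R5,18,senior,birads,4a+,80.0,80.8
R5,18,senior,birads,4b+,81.6,85.0
R5,18,senior,birads,4c+,64.1,65.0
R5,18,senior,bm,bm,85.0,85.0
R6,3,middle,birads,4a+,70.0,75.8
R6,3,middle,birads,4b+,79.1,84.2
R6,3,middle,birads,4c+,74.1,80.0
R6,3,middle,bm,bm,70.0,75.8
R7,10,senior,birads,4a+,64.1,64.2
R7,10,senior,birads,4b+,73.3,80.0
R7,10,senior,birads,4c+,64.1,70.0
R7,10,senior,bm,bm,73.3,80.8
R8,1,junior,birads,4a+,67.5,73.3
R8,1,junior,birads,4b+,57.5,69.2
R8,1,junior,birads,4c+,52.5,54.2
R8,1,junior,bm,bm,63.3,75.8
R9,1,junior,birads,4a+,66.6,71.6
R9,1,junior,birads,4b+,64.1,69.2
R9,1,junior,birads,4c+,56.6,57.5
R9,1,junior,bm,bm,62.5,65.8
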