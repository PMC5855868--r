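table,setting,batch,accuracy
gaussian,2,2,99.375
gaussian,3,2,99.375
gaussian,4,2,99.375
gaussian,5,2,99.375
gaussian,6,2,99.375
gaussian,7,2,99.375
gaussian,8,2,99.375
gaussian,9,2,99.375
gaussian,10,2,99.375
gaussian,2,3,99.375
gaussian,3,3,99.375
gaussian,4,3,99.375
gaussian,5,3,99.375
gaussian,6,3,99.375
gaussian,7,3,99.375
gaussian,8,3,99.375
gaussian,9,3,99.375
gaussian,10,3,99.375
gaussian,2,4,100
gaussian,3,4,100
gaussian,4,4,100
gaussian,5,4,98.75
gaussian,6,4,100
gaussian,7,4,98.75
gaussian,8,4,100
gaussian,9,4,97.5
gaussian,10,4,97.5
gaussian,2,5,75
gaussian,3,5,72.5
gaussian,4,5,75
gaussian,5,5,75
gaussian,6,5,75
gaussian,7,5,75
gaussian,8,5,73.75
gaussian,9,5,75
gaussian,10,5,75
gaussian,2,average,93.44
gaussian,3,average,92.81
gaussian,4,average,93.44
gaussian,5,average,93.13
gaussian,6,average,93.44
gaussian,7,average,93.13
gaussian,8,average,93.13
gaussian,9,average,92.81
gaussian,10,average,92.81
polynomial,2,2,98.75
polynomial,3,2,98.75
polynomial,4,2,99.375
polynomial,5,2,97.5
polynomial,6,2,98.75
polynomial,7,2,96.875
polynomial,8,2,98.125
polynomial,9,2,96.875
polynomial,10,2,93.75
polynomial,2,3,100
polynomial,3,3,100
polynomial,4,3,100
polynomial,5,3,100
polynomial,6,3,100
polynomial,7,3,100
polynomial,8,3,99.375
polynomial,9,3,100
polynomial,10,3,100
polynomial,2,4,100
polynomial,3,4,100
polynomial,4,4,100
polynomial,5,4,100
polynomial,6,4,100
polynomial,7,4,100
polynomial,8,4,100
polynomial,9,4,100
polynomial,10,4,100
polynomial,2,5,57.5
polynomial,3,5,62.5
polynomial,4,5,52.5
polynomial,5,5,52.5
polynomial,6,5,50
polynomial,7,5,50
polynomial,8,5,52.5
polynomial,9,5,48.75
polynomial,10,5,50
polynomial,2,average,89.06
polynomial,3,average,90.31
polynomial,4,average,87.97
polynomial,5,average,87.5
polynomial,6,average,87.19
polynomial,7,average,86.72
polynomial,8,average,87.5
polynomial,9,average,86.41
polynomial,10,average,85.94
sigmoid,2,2,98.75
sigmoid,3,2,96.875
sigmoid,4,2,98.75
sigmoid,5,2,96.25
sigmoid,6,2,98.75
sigmoid,7,2,91.25
sigmoid,8,2,91.875
sigmoid,9,2,93.125
sigmoid,10,2,96.25
sigmoid,2,3,96.875
sigmoid,3,3,98.75
sigmoid,4,3,99.375
sigmoid,5,3,100
sigmoid,6,3,100
sigmoid,7,3,100
sigmoid,8,3,100
sigmoid,9,3,99.375
sigmoid,10,3,100
sigmoid,2,4,100
sigmoid,3,4,100
sigmoid,4,4,100
sigmoid,5,4,100
sigmoid,6,4,98.75
sigmoid,7,4,100
sigmoid,8,4,100
sigmoid,9,4,100
sigmoid,10,4,93.75
sigmoid,2,5,71.25
sigmoid,3,5,70
sigmoid,4,5,70
sigmoid,5,5,70
sigmoid,6,5,71.25
sigmoid,7,5,67.5
sigmoid,8,5,72.5
sigmoid,9,5,70
sigmoid,10,5,68.75
sigmoid,2,average,91.72
sigmoid,3,average,91.41
sigmoid,4,average,92.03
sigmoid,5,average,91.56
sigmoid,6,average,92.19
sigmoid,7,average,89.69
sigmoid,8,average,91.09
sigmoid,9,average,90.63
sigmoid,10,average,89.69
controls,no_dealing,2,99.375
controls,pca,2,95.625
controls,lpp,2,90.625
controls,fda,2,96.875
controls,kfda,2,93.75
controls,qwkfda,2,99.375
controls,no_dealing,3,100
controls,pca,3,98.125
controls,lpp,3,61.25
controls,fda,3,71.25
controls,kfda,3,96.875
controls,qwkfda,3,99.375
controls,no_dealing,4,97.5
controls,pca,4,98.75
controls,lpp,4,93.75
controls,fda,4,91.25
controls,kfda,4,100
controls,qwkfda,4,100
controls,no_dealing,5,61.25
controls,pca,5,61.25
controls,lpp,5,75
controls,fda,5,62.5
controls,kfda,5,75
controls,qwkfda,5,75
controls,no_dealing,average,89.53
controls,pca,average,88.44
controls,lpp,average,80.16
controls,fda,average,80.47
controls,kfda,average,91.41
controls,qwkfda,average,93.44
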