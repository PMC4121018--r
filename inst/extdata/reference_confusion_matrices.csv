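classifier,true_class,granulation,slough,necrotic
bayes,granulation,192,21,9
bayes,slough,67,353,31
bayes,necrotic,5,15,74
svm_linear,granulation,184,35,3
svm_linear,slough,50,390,11
svm_linear,necrotic,14,34,46
svm_poly2,granulation,182,33,7
svm_poly2,slough,38,400,13
svm_poly2,necrotic,5,20,69
svm_poly3,granulation,195,23,4
svm_poly3,slough,31,410,10
svm_poly3,necrotic,3,16,75
svm_rbf,granulation,184,32,6
svm_rbf,slough,39,401,11
svm_rbf,necrotic,4,20,70
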