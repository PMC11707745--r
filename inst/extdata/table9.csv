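name_as_printed,name,bcs_class,pred_logP,pred_logD,pred_logPapp
acetaminophen,acetaminophen,1,0.523,0.406,-4.539
amiloride hydrochloride,amiloride hydrochloride,1,0.756,-0.372,-6.001
amoxicillin trihydrate,amoxicillin trihydrate,3,-0.286,-1.320,-6.340
antipyrine,antipyrine,1,0.588,0.156,-4.180
atenolol,atenolol,3,0.315,-0.987,-5.286
benserazide,benserazide,1,-2.197,-0.198,-6.586
varbamazepine,carbamazepine,2,2.313,1.881,-4.533
vephalexin,cephalexin,1,0.395,-1.030,-5.870
vimetidine,cimetidine,3,0.627,-0.688,-5.797
vreatinine,creatinine,3,-1.430,-1.288,-5.376
vyclosporine,cyclosporine,2,2.400,3.451,-5.822
d-glucose,d-glucose,1,-2.977,-2.276,-6.002
desipramine,desipramine,1,4.216,1.196,-4.840
enalapril maleate,enalapril maleate,1,1.040,-0.082,-5.357
enalaprilat,enalaprilat,3,-0.912,-1.177,-6.120
fexofenadine,fexofenadine,3,3.078,0.427,-5.190
fluvastatin,fluvastatin,1,3.890,1.705,-5.537
furosemide,furosemide,4,2.070,-0.890,-5.745
griseofulvin,griseofulvin,2,2.254,2.130,-4.300
hydrochlorothiazide,hydrochlorothiazide,3,-0.172,-0.008,-5.971
hydrocortisone,hydrocortisone,1,1.482,0.489,-5.030
isotretinoin,isotretinoin,2,6.240,3.307,-4.384
inogatran,inogatran,3,-0.156,-0.506,-6.120
ketoprofen,ketoprofen,2,3.261,0.023,-4.586
l-leucine,l-leucine,1,-1.624,-1.095,-5.167
l-dopa,l-dopa,1,-2.547,-1.006,-5.820
lisinopril,lisinopril,3,-1.850,-1.060,-6.426
losartan,losartan,3,3.437,3.701,-5.620
methyldopa,methyldopa,3,-2.359,0.194,-5.500
metoprolol,metoprolol,1,1.821,-0.195,-4.809
naproxen,naproxen,2,3.071,-0.079,-4.535
phenylalanine,phenylalanine,1,-1.412,-1.005,-5.145
piroxicam,piroxicam,2,2.852,-0.242,-4.850
propranolol,propranolol,1,3.152,0.827,-4.651
ranitidine,ranitidine,3,0.023,-0.930,-5.885
salicylic acid,salicylic acid,1,1.523,-0.922,-4.779
sulforaphane,sulforaphane,2,0.725,-0.619,-4.618
talinolol,talinolol,3,2.898,1.597,-5.237
terbutaline,terbutaline,3,0.512,-0.382,-5.527
triamcinolone acetonide,triamcinolone acetonide,2,2.329,1.653,-4.988
urea,urea,1,-1.781,-0.748,-4.992
valacyclovir,valacyclovir,1,-0.662,-1.059,-5.940
verapamil hydrochloride,verapamil hydrochloride,1,3.868,2.907,-5.010
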