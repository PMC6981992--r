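"code","label","category"
"B1","stay in unsafe areas","work areas"
"B2","enter into dangerous areas","work areas"
"B3","use overloaded machines","machinery"
"B4","unrecovered behavior B4 (placeholder label)","unlabelled"
"B5","unrecovered behavior B5 (placeholder label)","unlabelled"
"B6","operate machines and equipment against the procedures","machinery"
"B7","unrecovered behavior B7 (placeholder label)","unlabelled"
"B8","unrecovered behavior B8 (placeholder label)","unlabelled"
"B9","use machines and equipment without conforming safety beforehand","machinery"
"B10","use machines and equipment without effective safety devices","machinery"
"B11","implement inadequate protection measures for holes or borders","protection"
"B12","do not use all personal protective equipment (PPE)","PPE"
"B13","misuse personal protective equipment (PPE)","PPE"
"B14","engage in specialized operation without a permit","permits"
"B15","unrecovered behavior B15 (placeholder label)","unlabelled"
"B16","unrecovered behavior B16 (placeholder label)","unlabelled"
"B17","install or dismantle formwork support system against procedures","formwork"
"B18","install or dismantle machines and equipment against procedures","machinery"
"B19","unrecovered behavior B19 (placeholder label)","unlabelled"
"B20","unrecovered behavior B20 (placeholder label)","unlabelled"
"B21","unrecovered behavior B21 (placeholder label)","unlabelled"
"B22","concreting against procedures","concreting"
"B23","unrecovered behavior B23 (placeholder label)","unlabelled"
"B24","do not set up safety nets as required","protection"
"B25","unrecovered behavior B25 (placeholder label)","unlabelled"
"B26","unrecovered behavior B26 (placeholder label)","unlabelled"
"B27","issue improper commands","supervision"
"B28","unrecovered behavior B28 (placeholder label)","unlabelled"
"B29","unrecovered behavior B29 (placeholder label)","unlabelled"
"B30","unrecovered behavior B30 (placeholder label)","unlabelled"
"B31","do not hang warning signs in dangerous areas","work areas"
"B32","unrecovered behavior B32 (placeholder label)","unlabelled"
"B33","unrecovered behavior B33 (placeholder label)","unlabelled"
"B34","unrecovered behavior B34 (placeholder label)","unlabelled"
"B35","unrecovered behavior B35 (placeholder label)","unlabelled"
"B36","unrecovered behavior B36 (placeholder label)","unlabelled"
"B37","unrecovered behavior B37 (placeholder label)","unlabelled"
"B38","unrecovered behavior B38 (placeholder label)","unlabelled"
"B39","unrecovered behavior B39 (placeholder label)","unlabelled"
"B40","unrecovered behavior B40 (placeholder label)","unlabelled"
"B41","unrecovered behavior B41 (placeholder label)","unlabelled"
"B42","unrecovered behavior B42 (placeholder label)","unlabelled"
"B43","unrecovered behavior B43 (placeholder label)","unlabelled"
"B44","unrecovered behavior B44 (placeholder label)","unlabelled"
"B45","unrecovered behavior B45 (placeholder label)","unlabelled"
"B46","unrecovered behavior B46 (placeholder label)","unlabelled"
"B47","unrecovered behavior B47 (placeholder label)","unlabelled"
"B48","unrecovered behavior B48 (placeholder label)","unlabelled"
"B49","unrecovered behavior B49 (placeholder label)","unlabelled"
"B50","unrecovered behavior B50 (placeholder label)","unlabelled"
"B51","unrecovered behavior B51 (placeholder label)","unlabelled"
"B52","unrecovered behavior B52 (placeholder label)","unlabelled"
"B53","unrecovered behavior B53 (placeholder label)","unlabelled"
"B54","unrecovered behavior B54 (placeholder label)","unlabelled"
"B55","unrecovered behavior B55 (placeholder label)","unlabelled"
"B56","unrecovered behavior B56 (placeholder label)","unlabelled"
"B57","unrecovered behavior B57 (placeholder label)","unlabelled"
"B58","unrecovered behavior B58 (placeholder label)","unlabelled"
"B59","unrecovered behavior B59 (placeholder label)","unlabelled"
"B60","unrecovered behavior B60 (placeholder label)","unlabelled"
"B61","unrecovered behavior B61 (placeholder label)","unlabelled"
"B62","unrecovered behavior B62 (placeholder label)","unlabelled"
"B63","unrecovered behavior B63 (placeholder label)","unlabelled"
"B64","unrecovered behavior B64 (placeholder label)","unlabelled"
"B65","unrecovered behavior B65 (placeholder label)","unlabelled"
"B66","unrecovered behavior B66 (placeholder label)","unlabelled"
"B67","unrecovered behavior B67 (placeholder label)","unlabelled"
"B68","unrecovered behavior B68 (placeholder label)","unlabelled"
"B69","unrecovered behavior B69 (placeholder label)","unlabelled"
"B70","unrecovered behavior B70 (placeholder label)","unlabelled"
"B71","unrecovered behavior B71 (placeholder label)","unlabelled"
"B72","unrecovered behavior B72 (placeholder label)","unlabelled"
"B73","unrecovered behavior B73 (placeholder label)","unlabelled"
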