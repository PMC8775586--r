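# synthetic Gaussian stand-in for the green-channel optics transmission (peak 500 nm, HWHM 30 nm)
wavelength_nm,value
300,4.17724e-14
302,7.7114e-14
304,1.41482e-13
306,2.57985e-13
308,4.67532e-13
310,8.42078e-13
312,1.50736e-12
314,2.68168e-12
316,4.74155e-12
318,8.33217e-12
320,1.45519e-11
322,2.52584e-11
324,4.35729e-11
326,7.47052e-11
328,1.27294e-10
330,2.15572e-10
332,3.62827e-10
334,6.06919e-10
336,1.00899e-09
338,1.66711e-09
340,2.73759e-09
342,4.46783e-09
344,7.24684e-09
346,1.16822e-08
348,1.87165e-08
350,2.98023e-08
352,4.71627e-08
354,7.41774e-08
356,1.1595e-07
358,1.80132e-07
360,2.78122e-07
362,4.26781e-07
364,6.50877e-07
366,9.86545e-07
368,1.48614e-06
370,2.22498e-06
372,3.31067e-06
374,4.89588e-06
376,7.19565e-06
378,1.05107e-05
380,1.52588e-05
382,2.20156e-05
384,3.15695e-05
386,4.49911e-05
388,6.37251e-05
390,8.97055e-05
392,0.000125502
394,0.000174505
396,0.000241151
398,0.000331202
400,0.000452087
402,0.000613304
404,0.0008269
406,0.00110804
408,0.00147564
410,0.00195313
412,0.00256924
414,0.00335894
416,0.0043644
418,0.00563601
420,0.0072334
422,0.00922651
424,0.0116965
426,0.0147367
428,0.018453
430,0.0229646
432,0.0284037
434,0.0349152
436,0.0426559
438,0.0517926
440,0.0625
442,0.0749578
444,0.0893465
446,0.105843
448,0.124616
450,0.145816
452,0.169576
454,0.195995
456,0.225139
458,0.257028
460,0.291632
462,0.328862
464,0.368567
466,0.410529
468,0.454459
470,0.5
472,0.546726
474,0.594146
476,0.641713
478,0.688831
480,0.734867
482,0.779165
484,0.821058
486,0.859889
488,0.895025
490,0.925875
492,0.951905
494,0.972655
496,0.987753
498,0.996924
500,1
502,0.996924
504,0.987753
506,0.972655
508,0.951905
510,0.925875
512,0.895025
514,0.859889
516,0.821058
518,0.779165
520,0.734867
522,0.688831
524,0.641713
526,0.594146
528,0.546726
530,0.5
532,0.454459
534,0.410529
536,0.368567
538,0.328862
540,0.291632
542,0.257028
544,0.225139
546,0.195995
548,0.169576
550,0.145816
552,0.124616
554,0.105843
556,0.0893465
558,0.0749578
560,0.0625
562,0.0517926
564,0.0426559
566,0.0349152
568,0.0284037
570,0.0229646
572,0.018453
574,0.0147367
576,0.0116965
578,0.00922651
580,0.0072334
582,0.00563601
584,0.0043644
586,0.00335894
588,0.00256924
590,0.00195313
592,0.00147564
594,0.00110804
596,0.0008269
598,0.000613304
600,0.000452087
602,0.000331202
604,0.000241151
606,0.000174505
608,0.000125502
610,8.97055e-05
612,6.37251e-05
614,4.49911e-05
616,3.15695e-05
618,2.20156e-05
620,1.52588e-05
622,1.05107e-05
624,7.19565e-06
626,4.89588e-06
628,3.31067e-06
630,2.22498e-06
632,1.48614e-06
634,9.86545e-07
636,6.50877e-07
638,4.26781e-07
640,2.78122e-07
642,1.80132e-07
644,1.1595e-07
646,7.41774e-08
648,4.71627e-08
650,2.98023e-08
652,1.87165e-08
654,1.16822e-08
656,7.24684e-09
658,4.46783e-09
660,2.73759e-09
662,1.66711e-09
664,1.00899e-09
666,6.06919e-10
668,3.62827e-10
670,2.15572e-10
672,1.27294e-10
674,7.47052e-11
676,4.35729e-11
678,2.52584e-11
680,1.45519e-11
682,8.33217e-12
684,4.74155e-12
686,2.68168e-12
688,1.50736e-12
690,8.42078e-13
692,4.67532e-13
694,2.57985e-13
696,1.41482e-13
698,7.7114e-14
700,4.17724e-14
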