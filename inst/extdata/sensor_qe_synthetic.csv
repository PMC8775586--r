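# synthetic smooth quantum-efficiency ramp for a CMOS sensor (~30% near 365 nm, ~75% near 510 nm)
wavelength_nm,value
300,0.346253
302,0.347655
304,0.349094
306,0.350571
308,0.352086
310,0.353641
312,0.355236
314,0.356872
316,0.358549
318,0.360268
320,0.362029
322,0.363833
324,0.365681
326,0.367573
328,0.369509
330,0.371491
332,0.373518
334,0.375592
336,0.377711
338,0.379878
340,0.382091
342,0.384352
344,0.386661
346,0.389017
348,0.391422
350,0.393874
352,0.396374
354,0.398923
356,0.401519
358,0.404164
360,0.406856
362,0.409596
364,0.412383
366,0.415217
368,0.418097
370,0.421024
372,0.423995
374,0.427012
376,0.430073
378,0.433177
380,0.436323
382,0.439511
384,0.44274
386,0.446009
388,0.449316
390,0.45266
392,0.45604
394,0.459455
396,0.462903
398,0.466383
400,0.469893
402,0.473432
404,0.476999
406,0.480591
408,0.484206
410,0.487843
412,0.491501
414,0.495177
416,0.498868
418,0.502575
420,0.506293
422,0.510022
424,0.513759
426,0.517503
428,0.52125
430,0.525
432,0.52875
434,0.532497
436,0.536241
438,0.539978
440,0.543707
442,0.547425
444,0.551132
446,0.554823
448,0.558499
450,0.562157
452,0.565794
454,0.569409
456,0.573001
458,0.576568
460,0.580107
462,0.583617
464,0.587097
466,0.590545
468,0.59396
470,0.59734
472,0.600684
474,0.603991
476,0.60726
478,0.610489
480,0.613677
482,0.616823
484,0.619927
486,0.622988
488,0.626005
490,0.628976
492,0.631903
494,0.634783
496,0.637617
498,0.640404
500,0.643144
502,0.645836
504,0.648481
506,0.651077
508,0.653626
510,0.656126
512,0.658578
514,0.660983
516,0.663339
518,0.665648
520,0.667909
522,0.670122
524,0.672289
526,0.674408
528,0.676482
530,0.678509
532,0.680491
534,0.682427
536,0.684319
538,0.686167
540,0.687971
542,0.689732
544,0.691451
546,0.693128
548,0.694764
550,0.696359
552,0.697914
554,0.699429
556,0.700906
558,0.702345
560,0.703747
562,0.705112
564,0.706441
566,0.707735
568,0.708995
570,0.71022
572,0.711412
574,0.712572
576,0.7137
578,0.714797
580,0.715864
582,0.716901
584,0.717908
586,0.718888
588,0.719839
590,0.720764
592,0.721662
594,0.722534
596,0.723381
598,0.724204
600,0.725003
602,0.725778
604,0.726531
606,0.727261
608,0.72797
610,0.728658
612,0.729326
614,0.729973
616,0.730602
618,0.731211
620,0.731802
622,0.732375
624,0.732931
626,0.73347
628,0.733993
630,0.7345
632,0.734991
634,0.735467
636,0.735929
638,0.736376
640,0.736809
642,0.73723
644,0.737637
646,0.738031
648,0.738414
650,0.738784
652,0.739143
654,0.73949
656,0.739827
658,0.740153
660,0.740469
662,0.740775
664,0.741072
666,0.741359
668,0.741637
670,0.741906
672,0.742167
674,0.742419
676,0.742664
678,0.742901
680,0.74313
682,0.743352
684,0.743567
686,0.743775
688,0.743976
690,0.744171
692,0.74436
694,0.744542
696,0.744719
698,0.74489
700,0.745056
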