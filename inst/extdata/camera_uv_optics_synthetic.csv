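# synthetic Gaussian stand-in for the UV-channel optics transmission (peak 368 nm, HWHM 10 nm)
wavelength_nm,value
300,1.2033e-14
302,7.7114e-14
304,4.67532e-13
306,2.68168e-12
308,1.45519e-11
310,7.47052e-11
312,3.62827e-10
314,1.66711e-09
316,7.24684e-09
318,2.98023e-08
320,1.1595e-07
322,4.26781e-07
324,1.48614e-06
326,4.89588e-06
328,1.52588e-05
330,4.49911e-05
332,0.000125502
334,0.000331202
336,0.0008269
338,0.00195313
340,0.0043644
342,0.00922651
344,0.018453
346,0.0349152
348,0.0625
350,0.105843
352,0.169576
354,0.257028
356,0.368567
358,0.5
360,0.641713
362,0.779165
364,0.895025
366,0.972655
368,1
370,0.972655
372,0.895025
374,0.779165
376,0.641713
378,0.5
380,0.368567
382,0.257028
384,0.169576
386,0.105843
388,0.0625
390,0.0349152
392,0.018453
394,0.00922651
396,0.0043644
398,0.00195313
400,0.0008269
402,0.000331202
404,0.000125502
406,4.49911e-05
408,1.52588e-05
410,4.89588e-06
412,1.48614e-06
414,4.26781e-07
416,1.1595e-07
418,2.98023e-08
420,7.24684e-09
422,1.66711e-09
424,3.62827e-10
426,7.47052e-11
428,1.45519e-11
430,2.68168e-12
432,4.67532e-13
434,7.7114e-14
436,1.2033e-14
438,1.77636e-15
440,2.48088e-16
442,3.27791e-17
444,4.09739e-18
446,4.84546e-19
448,5.42101e-20
450,5.73777e-21
452,5.74544e-22
454,5.44279e-23
456,4.87795e-24
458,4.1359e-25
460,3.31758e-26
462,2.51762e-27
464,1.80749e-28
466,1.22766e-29
468,7.88861e-31
470,4.79556e-32
472,2.75801e-33
474,1.50062e-34
476,7.72434e-36
478,3.76158e-37
480,1.733e-38
482,7.55339e-40
484,3.11461e-41
486,1.21502e-42
488,4.48416e-44
490,1.56565e-45
492,5.17164e-47
494,1.61614e-48
496,4.77799e-50
498,1.33638e-51
500,3.53617e-53
502,8.85226e-55
504,2.09649e-56
506,4.69729e-58
508,9.95682e-60
510,1.99669e-61
512,3.78809e-63
514,6.79902e-65
516,1.15449e-66
518,1.8546e-68
520,2.81858e-70
522,4.05253e-72
524,5.51239e-74
526,7.09368e-76
528,8.63617e-78
530,9.9469e-80
532,1.08386e-81
534,1.11731e-83
536,1.08967e-85
538,1.00538e-87
540,8.77579e-90
542,7.247e-92
544,5.66172e-94
546,4.18462e-96
548,2.92605e-98
550,1.93564e-100
552,1.21139e-102
554,7.17237e-105
556,4.01752e-107
558,2.12898e-109
560,1.06734e-111
562,5.06233e-114
564,2.27152e-116
566,9.64274e-119
568,3.87259e-121
570,1.47137e-123
572,5.2888e-126
574,1.7985e-128
576,5.78606e-131
578,1.76105e-133
580,5.07083e-136
582,1.38135e-138
584,3.55996e-141
586,8.6797e-144
588,2.00208e-146
590,4.36895e-149
592,9.01964e-152
594,1.76165e-154
596,3.25512e-157
598,5.69026e-160
600,9.41055e-163
602,1.47237e-165
604,2.17938e-168
606,3.05189e-171
608,4.04317e-174
610,5.0675e-177
612,6.00872e-180
614,6.74043e-183
616,7.15338e-186
618,7.18212e-189
620,6.822e-192
622,6.13039e-195
624,5.21173e-198
626,4.19173e-201
628,3.1895e-204
630,2.29599e-207
632,1.56363e-210
634,1.00743e-213
636,6.14067e-217
638,3.54106e-220
640,1.93183e-223
642,9.97058e-227
644,4.86845e-230
646,2.24894e-233
648,9.82841e-237
650,4.06356e-240
652,1.58945e-243
654,5.88173e-247
656,2.05911e-250
658,6.81983e-254
660,2.1369e-257
662,6.33451e-261
664,1.77647e-264
666,4.71327e-268
668,1.18305e-271
670,2.80933e-275
672,6.31131e-279
674,1.34138e-282
676,2.69715e-286
678,5.13067e-290
680,9.23339e-294
682,1.57205e-297
684,2.53214e-301
686,3.85858e-305
688,5.56268e-309
690,7.58681e-313
692,9.7893e-317
694,1.19514e-320
696,0
698,0
700,0
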