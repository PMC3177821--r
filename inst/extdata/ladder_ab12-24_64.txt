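315.00
317.53
320.09
322.66
325.25
327.85
330.47
333.11
335.77
338.44
341.14
343.85
346.58
349.33
352.09
354.88
357.69
360.51
363.34
366.20
369.08
371.98
374.91
377.85
380.82
383.80
386.80
389.82
392.87
395.93
399.02
402.12
405.25
408.40
411.57
414.77
417.98
421.22
424.47
427.75
431.05
434.38
437.72
441.09
444.49
447.90
451.34
454.81
458.30
461.81
465.34
468.90
472.48
476.09
479.72
483.38
487.06
490.77
494.50
498.25
502.04
505.85
509.68
513.54
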