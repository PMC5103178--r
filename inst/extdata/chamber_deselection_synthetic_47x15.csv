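region_index,reason
1,chamber_edge
2,chamber_edge
3,chamber_edge
4,chamber_edge
5,chamber_edge
6,chamber_edge
7,chamber_edge
8,chamber_edge
9,chamber_edge
10,chamber_edge
11,chamber_edge
12,chamber_edge
13,chamber_edge
14,chamber_edge
15,chamber_edge
16,chamber_edge
30,chamber_edge
31,chamber_edge
45,chamber_edge
46,chamber_edge
60,chamber_edge
61,chamber_edge
75,chamber_edge
76,chamber_edge
90,chamber_edge
91,chamber_edge
105,chamber_edge
106,chamber_edge
120,chamber_edge
121,chamber_edge
135,chamber_edge
136,chamber_edge
150,chamber_edge
151,chamber_edge
165,chamber_edge
166,chamber_edge
180,chamber_edge
181,chamber_edge
195,chamber_edge
196,chamber_edge
210,chamber_edge
211,chamber_edge
225,chamber_edge
226,chamber_edge
240,chamber_edge
241,chamber_edge
255,chamber_edge
256,chamber_edge
260,oxygen_sensor
261,oxygen_sensor
262,oxygen_sensor
263,oxygen_sensor
264,oxygen_sensor
265,oxygen_sensor
270,chamber_edge
271,chamber_edge
275,oxygen_sensor
276,oxygen_sensor
277,oxygen_sensor
278,oxygen_sensor
279,oxygen_sensor
280,oxygen_sensor
285,chamber_edge
286,chamber_edge
290,oxygen_sensor
291,oxygen_sensor
292,oxygen_sensor
293,oxygen_sensor
294,oxygen_sensor
295,oxygen_sensor
300,chamber_edge
301,chamber_edge
305,oxygen_sensor
306,oxygen_sensor
307,oxygen_sensor
308,oxygen_sensor
309,oxygen_sensor
310,oxygen_sensor
315,chamber_edge
316,chamber_edge
320,oxygen_sensor
321,oxygen_sensor
322,oxygen_sensor
323,oxygen_sensor
324,oxygen_sensor
325,oxygen_sensor
330,chamber_edge
331,chamber_edge
335,oxygen_sensor
336,oxygen_sensor
337,oxygen_sensor
338,oxygen_sensor
339,oxygen_sensor
340,oxygen_sensor
345,chamber_edge
346,chamber_edge
350,oxygen_sensor
351,oxygen_sensor
352,oxygen_sensor
353,oxygen_sensor
354,oxygen_sensor
355,oxygen_sensor
360,chamber_edge
361,chamber_edge
365,oxygen_sensor
366,oxygen_sensor
367,oxygen_sensor
368,oxygen_sensor
369,oxygen_sensor
370,oxygen_sensor
375,chamber_edge
376,chamber_edge
380,oxygen_sensor
381,oxygen_sensor
382,oxygen_sensor
383,oxygen_sensor
384,oxygen_sensor
385,oxygen_sensor
390,chamber_edge
391,chamber_edge
395,oxygen_sensor
396,oxygen_sensor
397,oxygen_sensor
398,oxygen_sensor
399,oxygen_sensor
400,oxygen_sensor
405,chamber_edge
406,chamber_edge
410,oxygen_sensor
411,oxygen_sensor
412,oxygen_sensor
413,oxygen_sensor
414,oxygen_sensor
415,oxygen_sensor
420,chamber_edge
421,chamber_edge
425,oxygen_sensor
426,oxygen_sensor
427,oxygen_sensor
428,oxygen_sensor
429,oxygen_sensor
430,oxygen_sensor
435,chamber_edge
436,chamber_edge
440,oxygen_sensor
441,oxygen_sensor
442,oxygen_sensor
443,oxygen_sensor
444,oxygen_sensor
445,oxygen_sensor
450,chamber_edge
451,chamber_edge
465,chamber_edge
466,chamber_edge
480,chamber_edge
481,chamber_edge
495,chamber_edge
496,chamber_edge
510,chamber_edge
511,chamber_edge
525,chamber_edge
526,chamber_edge
540,chamber_edge
541,chamber_edge
555,chamber_edge
556,chamber_edge
570,chamber_edge
571,chamber_edge
585,chamber_edge
586,chamber_edge
600,chamber_edge
601,chamber_edge
615,chamber_edge
616,chamber_edge
630,chamber_edge
631,chamber_edge
645,chamber_edge
646,chamber_edge
660,chamber_edge
661,chamber_edge
675,chamber_edge
676,chamber_edge
690,chamber_edge
691,chamber_edge
692,chamber_edge
693,chamber_edge
694,chamber_edge
695,chamber_edge
696,chamber_edge
697,chamber_edge
698,chamber_edge
699,chamber_edge
700,chamber_edge
701,chamber_edge
702,chamber_edge
703,chamber_edge
704,chamber_edge
705,chamber_edge
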