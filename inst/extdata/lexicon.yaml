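# Coarse textual categories for the preliminary text classifier.
# Category order defines match priority (first match wins); UNKNOWN is the
# implicit pattern-free fallback. Patterns are matched as word-bounded
# substrings of the normalized concatenation of Series Description,
# Sequence Name, and Protocol Name.
version: 1
categories:
  - name: DWI-like
    patterns: [dwi, diff, ep2d diff, b0, b50, b500, b800, b850, b900, b950, b1000]
  - name: FLAIR/IR-like
    patterns: [flair, stir, tirm, dark fluid]
  - name: T1-like
    patterns: [t1, t1w, mprage, mp2rage, vibe, thrive, lava, fspgr, bravo]
  - name: T2-like
    patterns: [t2, t2w, haste, sstse, fiesta, bffe, trufi]
  - name: localiser-like
    patterns: [loc, localizer, localiser, scout, survey, smartbrain, cal,
               calibration, plan]
  - name: map/derived-like
    patterns: [adc, trace, map, mpr, sub, screenshot, screen, swi, pd, perf,
               dsc, resp, curve, fa, screensave]
ce_markers: ["+c", gd, km, post, gad, contrast, dotarem, gadovist, magnevist]
fs_markers: [fs, fatsat, spair, spir, stir]
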