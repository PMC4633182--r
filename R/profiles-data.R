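# Frozen per-species calibration table. Printed ratios carry
# sd = (max - min)/4 of the printed individual range; unprinted ratios were
# solved from the printed discriminant group-mean scores and key branch
# statistics (see the calibration section of the methods vignette).
.profile_rows <- list(
  list("angulinodis", "angulinodis", "EUROPE_MAINLAND", 12, 32, 38, 626, 15.75, 1.203, 0.01275, 0.368, 0.0055, 0.265, 0.00425, 0.374, 0.0055, 0.808, 0.00475, 0.621, 0.0065, 0.355, 0.00925, 0.285, 0.0105, 0.409, 0.00725, 0.386, 0.008, 1.2, 0.405, 0.26, 0.175, 0.25, 0.21, 0.42, 0.26, 0.28, 0.35, 0.16),
  list("angustifrons", "angustifrons", "ANATOLIA_OR_CRETE", 12, 47, 52, 546, 22.5, 1.224, 0.01525, 0.389, 0.006, 0.254, 0.004, 0.328, 0.00725, 0.821, 0.00625, 0.601, 0.008, 0.231, 0.016, 0.259, 0.00825, 0.298, 0.00925, 0.284, 0.00825, 1.22, 0.3634, 0.26, 0.148, 0.25, 0.21, 0.42, 0.26, 0.28, 0.35, 0.16),
  list("lucidus", "angustifrons", "ANATOLIA_OR_CRETE", 12, 47, 52, 618, 27.5, 1.173, 0.0205, 0.38, 0.008, 0.262, 0.00725, 0.37, 0.00825, 0.796, 0.01625, 0.621, 0.00925, 0.236, 0.01725, 0.258, 0.00975, 0.304, 0.01675, 0.29, 0.01425, 1.2, 0.3687, 0.26, 0.1675, 0.25, 0.21, 0.42, 0.26, 0.28, 0.35, 0.16),
  list("similis", "angustifrons", "ANATOLIA_OR_CRETE", 12, 47, 52, 571, 32.5, 1.183, 0.022, 0.386, 0.00675, 0.263, 0.00625, 0.361, 0.00425, 0.802, 0.01375, 0.624, 0.00875, 0.245, 0.01175, 0.277, 0.00725, 0.321, 0.012, 0.321, 0.00875, 1.25, 0.3511, 0.26, 0.148, 0.25, 0.21, 0.42, 0.26, 0.28, 0.35, 0.16),
  list("subtilis", "angustifrons", "ANATOLIA_OR_CRETE", 12, 47, 52, 556, 32.25, 1.189, 0.02575, 0.388, 0.0085, 0.249, 0.01, 0.36, 0.01, 0.782, 0.01875, 0.623, 0.014, 0.192, 0.01775, 0.272, 0.01325, 0.282, 0.0175, 0.282, 0.0165, 1.2053, 0.3581, 0.26, 0.15, 0.25, 0.21, 0.42, 0.26, 0.28, 0.35, 0.16),
  list("flavicornis", "flavicornis", "EUROPE_MAINLAND", 11, 38, 45, 496, 12.75, 1.266, 0.01825, 0.384, 0.006, 0.262, 0.00675, 0.364, 0.0055, 0.803, 0.00825, 0.637, 0.00775, 0.358, 0.02925, 0.338, 0.009, 0.458, 0.026, 0.432, 0.02725, 1.2, 0.385, 0.26, 0.172, 0.25, 0.21, 0.42, 0.26, 0.28, 0.35, 0.16),
  list("laconicus", "lichtensteini", "EUROPE_MAINLAND", 12, 20, 25, 546, 22.5, 1.228, 0.01475, 0.396, 0.005, 0.244, 0.009, 0.342, 0.00775, 0.785, 0.0095, 0.61, 0.0105, 0.411, 0.0095, 0.283, 0.0135, 0.438, 0.021, 0.413, 0.02025, 1.2, 0.385, 0.26, 0.175, 0.25, 0.21, 0.42, 0.26, 0.28, 0.35, 0.16),
  list("lichtensteini", "lichtensteini", "EUROPE_MAINLAND", 12, 20, 25, 535, 27.75, 1.225, 0.02, 0.401, 0.008, 0.248, 0.0095, 0.356, 0.011, 0.787, 0.0115, 0.608, 0.01525, 0.346, 0.01325, 0.272, 0.013, 0.391, 0.02325, 0.371, 0.02325, 1.2, 0.385, 0.26, 0.177, 0.25, 0.21, 0.42, 0.26, 0.28, 0.35, 0.16),
  list("nylanderi", "nylanderi", "CENTRAL_WEST_EUROPE", 12, 32, 42, 625, 22.75, 1.14, 0.00975, 0.391, 0.00575, 0.254, 0.00575, 0.373, 0.00725, 0.777, 0.01025, 0.624, 0.009, 0.28, 0.008, 0.28, 0.00775, 0.343, 0.01025, 0.32, 0.01025, 1.2, 0.385, 0.26, 0.172, 0.25, 0.21, 0.42, 0.26, 0.28, 0.35, 0.16),
  list("crassispinus", "nylanderi", "EUROPE_MAINLAND", 12, 32, 42, 623, 36.0, 1.14, 0.02, 0.39, 0.006, 0.256, 0.00525, 0.377, 0.00925, 0.784, 0.01375, 0.626, 0.03825, 0.329, 0.017, 0.312, 0.01425, 0.389, 0.01475, 0.366, 0.01375, 1.2, 0.372, 0.26, 0.172, 0.25, 0.21, 0.42, 0.26, 0.28, 0.35, 0.1558),
  list("crasecundus", "nylanderi", "EAST_EUROPE_BALKANS_CAUCASUS", 12, 32, 42, 614, 45.0, 1.155, 0.01875, 0.39, 0.00675, 0.255, 0.011, 0.374, 0.0095, 0.791, 0.01825, 0.617, 0.01125, 0.289, 0.01725, 0.298, 0.0105, 0.35, 0.02025, 0.331, 0.01725, 1.2, 0.385, 0.26, 0.17, 0.25, 0.21, 0.42, 0.26, 0.28, 0.35, 0.1609),
  list("parvulus", "parvulus", "EUROPE_MAINLAND", 12, 38, 42, 550, 24.5, 1.184, 0.01675, 0.405, 0.00525, 0.25, 0.00625, 0.361, 0.00575, 0.778, 0.00825, 0.618, 0.00925, 0.306, 0.01325, 0.292, 0.00975, 0.384, 0.0155, 0.364, 0.01575, 1.2, 0.385, 0.2517, 0.15, 0.25, 0.21, 0.42, 0.26, 0.28, 0.35, 0.16),
  list("ariadnae", "parvulus", "ANATOLIA_OR_CRETE", 12, 38, 42, 543, 6.0, 1.223, 0.02425, 0.386, 0.005, 0.263, 0.0015, 0.356, 0.00575, 0.775, 0.00925, 0.611, 0.004, 0.237, 0.00725, 0.278, 0.00975, 0.314, 0.00825, 0.3, 0.00825, 1.2, 0.385, 0.26, 0.172, 0.238, 0.21, 0.4621, 0.26, 0.28, 0.35, 0.16),
  list("helenae", "parvulus", "EUROPE_MAINLAND", 12, 38, 42, 566, 29.25, 1.197, 0.0225, 0.4, 0.01, 0.251, 0.008, 0.357, 0.0095, 0.783, 0.0125, 0.611, 0.0135, 0.255, 0.0235, 0.281, 0.016, 0.334, 0.02425, 0.32, 0.02325, 1.187, 0.385, 0.2558, 0.152, 0.25, 0.21, 0.4335, 0.26, 0.28, 0.35, 0.16),
  list("artvinensis", "sordidulus", "ANATOLIA_OR_CRETE", 12, 42, 48, 582, 23.5, 1.24, 0.01425, 0.374, 0.006, 0.247, 0.00525, 0.367, 0.0045, 0.794, 0.00925, 0.612, 0.007, 0.265, 0.01525, 0.278, 0.009, 0.331, 0.0135, 0.313, 0.01425, 1.2, 0.385, 0.2815, 0.17, 0.266, 0.21, 0.42, 0.26, 0.28, 0.35, 0.16),
  list("schoedli", "sordidulus", "ANATOLIA_OR_CRETE", 12, 42, 48, 652, 31.0, 1.172, 0.01325, 0.368, 0.00625, 0.268, 0.00675, 0.372, 0.004, 0.784, 0.01025, 0.632, 0.00925, 0.261, 0.0125, 0.288, 0.004, 0.327, 0.00925, 0.31, 0.00875, 1.2, 0.385, 0.246, 0.168, 0.25, 0.21, 0.42, 0.26, 0.28, 0.35, 0.16),
  list("sordidulus", "sordidulus", "EUROPE_MAINLAND", 12, 42, 48, 574, 22.25, 1.238, 0.0215, 0.374, 0.00675, 0.266, 0.0055, 0.366, 0.00625, 0.785, 0.0115, 0.615, 0.01025, 0.258, 0.0135, 0.273, 0.0085, 0.306, 0.01275, 0.288, 0.0115, 1.2628, 0.385, 0.2461, 0.17, 0.28, 0.21, 0.428, 0.26, 0.28, 0.35, 0.16),
  list("tergestinus", "sordidulus", "EUROPE_MAINLAND", 12, 42, 48, 592, 35.5, 1.206, 0.021, 0.384, 0.00675, 0.258, 0.01075, 0.361, 0.00825, 0.799, 0.01075, 0.62, 0.016, 0.276, 0.02875, 0.273, 0.01175, 0.333, 0.02225, 0.312, 0.019, 1.2506, 0.385, 0.2468, 0.17, 0.26, 0.21, 0.405, 0.26, 0.28, 0.35, 0.16)
)
.profile_cols <- c("species", "complex", "region", "antennomere_count", "spine_angle_lo", "spine_angle_hi", "cs_mean", "cs_sd", "CL.CWb_mean", "CL.CWb_sd", "PoOC.CL_mean", "PoOC.CL_sd", "EL_mean", "EL_sd", "FRS_mean", "FRS_sd", "SL_mean", "SL_sd", "MW_mean", "MW_sd", "SPST_mean", "SPST_sd", "SPBA_mean", "SPBA_sd", "SPWI_mean", "SPWI_sd", "SPTI_mean", "SPTI_sd", "ML_mean", "PEH_mean", "PEW_mean", "NOH_mean", "NOL_mean", "NOdL_mean", "PL_mean", "PPH_mean", "PPL_mean", "PPW_mean", "SPL_mean")
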