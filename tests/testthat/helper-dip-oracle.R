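# Frozen reference values for the dip statistic on small datasets.
# Each value is the minimax sup-distance from the empirical CDF to the
# nearest unimodal CDF, computed by an independent linear-programming
# minimisation over piecewise-linear unimodal CDFs: every mode placement
# (at data points with an atom allowed, and inside each support gap with
# the mode position optimised by grid refinement), solved to ~1e-9.
dip_oracle_cases <- list(
  list(name = "equal_spaced_5", x = c(1, 2, 3, 4, 5), dip = 0.09999999999999998),
  list(name = "equal_spaced_12", x = c(0, 1, 2, 3, 4, 5, 6, 7, 8, 9, 10, 11), dip = 0.04166666666666659),
  list(name = "two_point_6", x = c(0, 0, 0, 1, 1, 1), dip = 0.25),
  list(name = "two_point_skew", x = c(0, 0, 0, 0, 0, 0, 0, 0, 0, 1), dip = 0.050000000000000044),
  list(name = "ordinal_a", x = c(1, 1, 1, 2, 2, 3, 4, 4), dip = 0.125),
  list(name = "ordinal_b", x = c(1, 1, 2, 2, 3, 3, 4, 4), dip = 0.12499999999999999),
  list(name = "ordinal_c", x = c(1, 1, 1, 1, 4, 4, 4, 4, 4), dip = 0.2222222222222222),
  list(name = "two_clusters", x = c(0.5, 0.7, 0.9, 1.1, 1.3, 1.5, 3.5, 3.7, 3.9, 4.1, 4.3, 4.5), dip = 0.16666666666666596),
  list(name = "norm_0", x = c(-2.0346, 0.6033, 0.7443, -0.3097, 0.3673, 1.7104), dip = 0.08333333333333331),
  list(name = "norm_1", x = c(1.0608, 0.7076, 0.6877, -0.8636, 0.964, -1.6485, -0.3321, -0.4373, -1.7285, -0.1103, 1.6435, -0.3401), dip = 0.11356843992827198),
  list(name = "norm_2", x = c(-0.0911, 0.8539, 0.1932, -0.0027, -1.4092, 0.501, 0.4857, 1.3413), dip = 0.09626386962552005),
  list(name = "norm_3", x = c(1.4891, 0.6886, -1.6424, -1.4354, -1.098, 0.2949, -0.7872), dip = 0.10474706212611068),
  list(name = "norm_4", x = c(0.2439, 0.3648, 0.7505, 0.3402, -1.4106, 2.4519, 1.463, 1.5231, -0.7475, -1.8475, -1.5066), dip = 0.09838124961965444),
  list(name = "norm_5", x = c(-1.0535, 0.8821, 0.9003, 1.4584, 2.1424, 0.5209, 0.3546, -0.363), dip = 0.08559241706161125),
  list(name = "norm_6", x = c(-1.1578, 0.5108, 0.3182, -0.4052), dip = 0.125),
  list(name = "norm_7", x = c(-0.8106, 0.457, 1.3062, 0.0815, 0.2838, -0.5482, -0.2485, -0.3165, -0.2851), dip = 0.0779588944011338),
  list(name = "norm_8", x = c(0.3964, 1.2997, -0.9472, 1.3992, -0.403, -0.3671, -2.1565, -2.4215, 0.7355, -1.0911, 0.8053, 0.0506), dip = 0.07341066757648126),
  list(name = "norm_9", x = c(0.2505, 1.3333, -0.0724, -3.2661, -1.7386, 0.9726, 1.9967, -0.096), dip = 0.08336026967122265),
  list(name = "norm_10", x = c(-1.3922, 0.5461, -1.7979, -1.2458, 0.1359, 0.1019, -0.2588, 1.0634), dip = 0.12024072509908366),
  list(name = "norm_11", x = c(-1.2434, -1.1908, -0.4184, 0.0651, -0.3378, 1.9927, -0.6039, 0.6353, -0.5864, 0.3207), dip = 0.0917748240813135),
  list(name = "bimod_0", x = c(-3.1572, -2.3505, 2.8652, 3.6869, 2.7042), dip = 0.1724741529327464),
  list(name = "bimod_1", x = c(-3.1875, -2.5562, 2.0081, 2.3305), dip = 0.2196233351297251),
  list(name = "bimod_2", x = c(-2.8092, -2.7709, 2.8696, 2.4219, 3.3338), dip = 0.1985356808319474),
  list(name = "bimod_3", x = c(-2.8215, -3.4565, -2.9655, 3.7285, 3.0495, 2.5188, 2.8268), dip = 0.19151339681689597),
  list(name = "bimod_4", x = c(-2.8625, -2.6345, -3.3801, -3.2652, -2.5877, 3.299, 3.5491, 2.4056, 2.6101, 3.407), dip = 0.2034162755833654),
  list(name = "bimod_5", x = c(-3.3876, -2.8696, 2.9765, 2.695), dip = 0.22870976227271234),
  list(name = "bimod_6", x = c(-3.0074, -3.2078, -3.0664, -2.9005, -3.6424, 2.647, 2.4774, 2.1422, 3.3963, 3.5822), dip = 0.19446758295154737),
  list(name = "bimod_7", x = c(-2.5175, -3.7222, -2.8392, -2.725, -3.2336, -2.6691, 2.5442, 2.5612, 2.6593, 2.7048, 2.5881, 3.3889), dip = 0.2019381143878451),
  list(name = "ord_0", x = c(3, 1, 1, 2, 4, 4), dip = 0.16666666666666666),
  list(name = "ord_1", x = c(4, 1, 2, 1, 3, 2, 1), dip = 0.1428571428571429),
  list(name = "ord_2", x = c(4, 1, 2, 4, 3, 1, 2, 4, 4, 3, 1), dip = 0.13636363636363635),
  list(name = "ord_3", x = c(4, 1, 1, 2), dip = 0.125),
  list(name = "ord_4", x = c(1, 4, 3, 2, 2, 1, 3, 4), dip = 0.12499999999999999),
  list(name = "ord_5", x = c(3, 4, 2, 1, 2, 3), dip = 0.16666666666666663),
  list(name = "ord_6", x = c(3, 2, 4, 4), dip = 0.125),
  list(name = "ord_7", x = c(1, 2, 3, 2, 2, 2, 1, 1, 4, 3, 1, 4), dip = 0.16666666666666663)
)
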