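# Amino-acid substitution model constants.
#
# Exchangeabilities and stationary frequencies of the WAG model (Whelan &
# Goldman 2001, Mol Biol Evol 18:691-699), the fixed empirical model used for
# sequence simulation and likelihood computation throughout the package.
# Residue order is the standard A R N D C Q E G H I L K M F P S T W Y V;
# the exchangeability vector is the lower triangle, column-wise.

AA_ALPHABET <- c("A","R","N","D","C","Q","E","G","H","I",
                 "L","K","M","F","P","S","T","W","Y","V")

WAG_EXCHANGE <- c(
  0.55157100000000003, 0.50984799999999997, 0.73899800000000004,            1.02704,
  0.90859800000000002, 1.5828500000000001,            1.41672, 0.31695400000000001,
  0.19333500000000001, 0.39791500000000002, 0.90626499999999999, 0.89349599999999996,
  0.21049399999999999,            1.43855,            3.37079, 2.1211099999999998,
            0.113133,           0.240735, 2.0060099999999998, 0.63534599999999997,
  0.14730399999999999, 0.52819099999999997, 3.0354999999999999, 0.43915700000000002,
  0.58466499999999999, 2.1371500000000001, 0.18697900000000001, 0.49767099999999997,
  5.3514200000000001, 0.68316200000000005,           0.102711, 0.67948900000000001,
  1.2241899999999999, 0.55441300000000004, 1.1639200000000001, 0.38153300000000001,
  0.25184899999999999, 5.4294200000000004, 0.26525599999999999, 1.5436399999999999,
  0.94719799999999998, 1.1255599999999999, 3.9562900000000001, 0.55423599999999995,
  0.13152800000000001, 3.0120100000000001, 0.19822100000000001,          0.0961621,
            0.195081, 3.9742299999999999, 2.0300600000000002,          0.0719167,
  1.0860000000000001,           0.196246,          0.0302949, 0.61678299999999997,
  6.1741599999999996, 0.86558400000000002, 0.93067599999999995,           0.039437,
  0.084804699999999997, 0.47985499999999998,           0.103754, 0.046730399999999998,
  0.42398400000000003,            1.07176, 0.37486599999999998, 0.12976699999999999,
  0.32571099999999997,           0.152335,          0.0988179, 0.021351999999999999,
            0.306674,           0.248972, 0.17013500000000001, 0.38428699999999999,
           0.0740339,           0.390482, 0.39801999999999998,           0.109404,
  1.4076599999999999,           0.512984, 0.71706999999999999, 0.54383300000000001,
             1.00214, 5.4694700000000003, 0.33005200000000001, 4.2941099999999999,
            0.113917, 0.86948899999999996, 3.8948999999999998, 1.5452600000000001,
  0.099920800000000004, 0.93337199999999998,            1.02887, 0.85792800000000002,
  0.21573700000000001,            0.22771, 0.30128100000000002, 0.56771700000000003,
            0.570025, 0.12739500000000001, 0.15426300000000001, 2.5844299999999998,
  0.31512400000000002, 0.081133899999999995, 0.68235500000000004, 0.70493899999999998,
  0.82276499999999997,           0.156557, 0.19630300000000001,           0.588731,
  0.24940999999999999, 0.030450100000000001, 0.061303700000000003,           0.373558,
              0.1741, 0.049931000000000003, 0.24357000000000001,            1.34182,
  0.22583300000000001, 0.33698299999999998,           0.103604,           0.187247,
  0.13819000000000001, 0.49946200000000002,           0.890432, 0.40414099999999997,
  0.67937099999999995, 0.69619799999999998, 0.74016899999999997, 0.47330699999999998,
            0.262569,            3.87344,           0.118358, 3.1709700000000001,
  0.32383200000000001,            4.25746, 1.0594699999999999, 0.099928799999999998,
             0.31944, 1.4581599999999999, 0.21248300000000001, 0.42016999999999999,
  7.8212999999999999, 0.25755499999999998, 4.8540200000000002,            2.11517,
  0.41584399999999999, 0.34473900000000002, 0.32662200000000002, 0.66530900000000004,
  0.39861799999999997, 1.8003400000000001,           0.934276, 0.088835999999999998,
  0.55689599999999995, 0.96713000000000005, 1.3869800000000001, 0.13750499999999999,
  0.13326399999999999, 0.30543399999999998, 1.1906300000000001, 0.17132900000000001,
  0.49390499999999998, 1.5161199999999999,           0.515706, 0.42843700000000001,
  2.0584500000000001,           0.161444, 0.54593100000000006,           0.171903,
  1.5296400000000001, 6.4542799999999998, 0.64989200000000003,            1.61328,
  0.79538399999999998,           0.139405, 0.21604599999999999, 0.31488699999999997,
  4.3780200000000002, 0.52374200000000004, 0.78699300000000005,           0.232739,
            0.110864, 0.29114800000000002, 1.3882300000000001, 2.4853900000000002,
            0.365369, 0.31473000000000001
)

WAG_FREQ <- c(
  0.086627908662790867, 0.043972004397200441, 0.039089403908940397, 0.057045105704510574,
  0.019307801930780195, 0.036728103672810368, 0.058058905805890577, 0.083251808325180837,
  0.024431302443130246, 0.048466004846600491, 0.086209008620900862, 0.062028606202860624,
  0.019502701950270197, 0.038431903843190382, 0.045763104576310464, 0.069517906951790692,
  0.061012706101270617, 0.014385901438590145, 0.035274203527420354, 0.070895607089560719
)
names(WAG_FREQ) <- AA_ALPHABET

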