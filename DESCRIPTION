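Package: castehub
Title: Augmented Small-Sample Expression Classification and Hub-Gene Scoring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for classifying phenotype classes (honeybee castes:
    queen, worker, drone) from small-n, high-dimensional expression
    matrices. Expands each class with a four-way augmentation mixture
    built around a Wasserstein GAN with gradient penalty (WGAN-GP),
    plus SMOTE interpolation, Gaussian jitter and within-class Mixup,
    guarded by a distance-based plausibility filter. Classifies with a
    hybrid windowed-attention/depthwise-convolution network whose two
    branches are fused by learnable scalar weights, trained with AdamW,
    warmup plus cosine annealing, label smoothing, Mixup and early
    stopping. Attributes predictions to genes with Gradient x Input,
    combines attribution with co-expression network scores (gene
    significance, module membership) and ranks hub genes overall and
    per class. Ships a synthetic caste-expression generator with known
    ground truth so the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    rlang,
    readr,
    ggplot2,
    generics,
    yaml,
    class,
    e1071,
    nnet,
    randomForest
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    igraph
Config/testthat/edition: 3
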