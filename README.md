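# gastroq

Reward-driven classification and attention-gated segmentation of
gastrointestinal endoscopy images, in R.

Gastrointestinal screening produces large volumes of endoscopy frames in
which clinically relevant findings (ulcers, polyps, inflamed mucosa) must
first be *recognized* and then *delineated*. `gastroq` implements a
two-phase pipeline for this problem:

1. **Classification.** A compact CNN — conv(32, 3×3)/ReLU/maxpool,
   conv(64, 3×3)/ReLU/maxpool, flatten, dense(64)/ReLU — is pretrained
   from scratch and frozen; its 64-d embedding *f* becomes the **state**
   of a tabular Q-learning agent whose **actions** are the class labels.
   The agent learns with the Bellman update

   *Q(s,a) ← Q(s,a) + α [ r + γ·maxₐ′ Q(s′,a′) − Q(s,a) ]*

   under an ε-greedy policy, receiving +1 for a correct prediction and −1
   otherwise (defaults α = 0.1, γ = 0.6, ε = 0.1, 1000 episodes × 100
   steps). States are discretized by per-feature median exceedance into
   64-bit keys; test-time prediction is purely greedy.

2. **Segmentation.** An attention-gated U-Net (depth 4, base 16 filters,
   transposed-conv upsampling) segments lesions. Each skip is rescaled by
   additive-attention coefficients *α = σ(ψ ReLU(W_f x + up(W_g g) + b))*
   before concatenation; training minimizes pixel-wise binary
   cross-entropy with Adam (batch 8, 50 epochs by default). Quality is
   scored by Dice, IoU (with an ε-stabilized union) and pixel accuracy.

There is no deep-learning framework underneath: convolution, pooling,
transposed convolution and bilinear resizing (forward *and* backward) are
compiled Rcpp/Armadillo kernels, and both networks train by explicit
backpropagation — fully deterministic under a seed.

The package also ships the surrounding protocol: per-class-folder and
image/mask loaders, exact `I/255` normalization, flip augmentation that
doubles a dataset (one seeded horizontal/vertical flip per record),
stratified 0.5 hold-out splitting, confusion-matrix/precision/recall/F1
reports, deterministic synthetic fixture generators, broom-style
`tidy()`/`glance()` methods, `autoplot()` figures, and a `gastroq`
command-line entry point (`exec/gastroq`).

## Worked example

Train the full classification phase on the built-in synthetic fixture
(4 separable texture/color classes, 50 images each, 64×64):

```r
library(gastroq)

spec  <- fixture_spec("classification", num_classes = 4, n_per_class = 50,
                      image_size = 64, seed = 2024)
recs  <- generate_classification_records(spec)
split <- holdout_split(recs, fraction = 0.5, seed = 1)

cnn <- build_cnn(cnn_config(num_classes = 4), seed = 1)
cnn <- pretrain_cnn(cnn, split$train, pretrain_config(epochs = 5, seed = 1))
tidy(cnn)
#>   epoch   loss accuracy
#>       1 1.397      0.25
#>       2 0.279      0.83
#>       3 0.120      1.00
#>       4 0.034      1.00
#>       5 0.016      1.00

tr    <- extract_feature_matrix(cnn, split$train)
agent <- train_agent(tr$features, tr$labels, q_config(episodes = 200, seed = 1))
te    <- extract_feature_matrix(cnn, split$test)
ev    <- evaluate_agent(agent, te$features, te$labels)
ev$accuracy       # 100  (percent correct on the held-out half)
ev$unseen_rate    # 0    (every test state was visited during training)
ev$report$confusion
#>      predicted
#> truth  0  1  2  3
#>     0 25  0  0  0
#>     1  0 25  0  0
#>     2  0  0 25  0
#>     3  0  0  0 25
autoplot(agent)   # reward-per-episode curve (rises ~82 -> ~85 of max 100)
```

The pretraining history shows the supervised stage converging on the
separable fixture; the agent then maps every held-out embedding onto a
state key it learned during training (unseen rate 0), giving a diagonal
confusion matrix. The segmentation phase is one call chain away:

```r
sspec <- fixture_spec("segmentation", n = 200, image_size = 64, seed = 11)
pairs <- generate_segmentation_records(sspec)
sp    <- holdout_split(pairs, 0.5, seed = 7)
unet  <- build_attention_unet(unet_config(input_size = 64), seed = 1)
unet  <- train_segmenter(unet, sp$train,
                         seg_train_config(epochs = 10, seed = 1),
                         validation = sp$test)
glance(unet)
#>   epochs final_loss final_val_loss final_val_dice best_val_dice
#>       10    0.00835        0.00933          0.982         0.982
```

Validation Dice reaches 0.98 within 10 epochs on the ellipse fixture;
`predict_mask()` returns the probability map and the 0.5-thresholded
binary mask, and `evaluate_segmenter()` the per-image Dice/IoU/pixel
accuracy. From a shell, the same pipeline is
`gastroq pipeline --seed 1 --out runs/demo`.

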