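---
title: "Decoding music listening versus recall states from EEG with steady-state activation maps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding music listening versus recall states from EEG with steady-state activation maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(ssam)
```

## The problem

When a person passively listens to a melody and when they internally
recall and continue one, the two cognitive states leave different
signatures in scalp EEG. `ssam` implements a complete pipeline for
separating these two states from 32-channel recordings (international
10--20 montage), and -- just as importantly -- for reading back *which*
scalp regions and frequency bands carried the distinction. The working
hypothesis behind the architecture is neuroscientific: brain regions
engaged by a sustained internal task stay activated over many seconds, so
a classifier should aggregate evidence over time into a *steady-state*
spatial picture rather than chase individual windows.

## From raw signal to model input

Trials are band-limited into the four awake-cognition bands
(theta 4--7 Hz, alpha 8--13 Hz, beta 14--30 Hz, gamma 31--45 Hz) with a
third-order Butterworth filter, applied forward--backward
(`signal::filtfilt`) so that filtering is zero-phase and the one-second
feature windows stay aligned with the raw signal. The gamma band is
defined as 31--45 Hz throughout: this is the definition that governs the
model input, and it keeps the band clear of 50 Hz mains interference,
which is separately removed by a biquad notch (quality factor 30; the
notch places an exact spectral zero at the target frequency). An optional
artifact hook is exposed on `decompose_bands()` for users who want to
insert an ICA-based cleanup; the package itself ships none, because
component selection requires human judgment and the synthetic data
contains no artifacts. Recordings acquired at other rates (EEG amplifiers
commonly sample at 200 Hz or more) are brought to the 128 Hz model rate
by polyphase resampling (`resample_recording()`); the synthetic generator
emits 128 Hz directly.

Each band signal is cut into non-overlapping 1 s windows (trailing
partial windows are dropped, never padded) and each window is summarized
per channel by its differential entropy, using the Gaussian closed form

$$\mathrm{DE}(x) = \tfrac{1}{2}\,\ln\!\big(2\pi e\,\hat\sigma^2\big),$$

with the unbiased $(n-1)$ variance estimator, in nats. Two consequences
of this closed form are used as test oracles: for N(0,1) samples the
expected value is $\tfrac12\ln(2\pi e) \approx 1.4189$, and scaling a
window by $c$ shifts its DE by exactly $\ln c$. The 32 DE values of each
window are embedded into a 9x9 matrix whose geometry mirrors the scalp
(anterior rows first, left hemisphere in the left columns, midline in
column 5, mastoids at the lateral ends of the central row); the 49 cells
without an electrode are identically zero. The layout ships as a
versioned CSV (`inst/extdata/grid_layout_v1.csv`) and any alternative
satisfying the same structural invariants can be supplied.

## The network

Per band $b$, the input is the sequence of 9x9 frames
$D^b = \{m(1), \dots, m(T)\}$. The stages are:

1. **Per-frame spatial self-attention.** Two learned 1x1 projections
   $W_G, W_F$ embed each grid cell's scalar value; attention scores are
   inner products of the embeddings, softmax-normalized over the attended
   (key) positions, and the frame is recalibrated as the
   attention-weighted combination $Z(i,j) = \sum_{p,q} a_{(i,j),(p,q)}
   m(p,q)$. Because the projections act on scalars, each attention row
   depends on the cell's value only; the C++ training kernel exploits
   this (cells sharing a value share their attention row, and the exact
   parameter gradient reduces to two attention-variance statistics),
   which is what makes 50-epoch ten-fold cross-validation cheap on one
   CPU. The embedding width (default 8) only enriches the
   parametrization; it is deliberately configurable and small.
2. **Frame importance.** An alignment vector is computed as a learned
   linear map of the time-averaged recalibrated frame (the operand is not
   uniquely pinned down by the architecture's description; the
   time-average is the minimal choice and is isolated in one function).
   Each frame is scored through a one-hidden-layer ELU network against
   this alignment vector, and the score inner products are
   softmax-normalized into weights $\alpha_t$.
3. **Steady-state activation map.** $S^b = \sum_t \alpha_t Z_t$ -- the
   importance-weighted temporal aggregate. A stray factor in the printed
   formula for this sum is treated as typographical.
4. **CNN spatial encoding.** Three 3x3 convolutions (32/64/128 filters by
   default, zero padding, stride 1, spatial size preserved) with SELU
   activations, with a separate filter bank per band so band information
   cannot mix before the fusion stage. Padding is not specified in the
   architecture description; "same" zero padding is the natural choice
   that preserves the 9x9 geometry.
5. **Efficient channel attention (ECA).** Global average pooling over the
   grid, a 1-D convolution across channels whose kernel size follows
   $k = |\log_2(C)/\lambda + b/\lambda|$ with $\lambda = 2$, $b = 1$,
   rounded to the *nearest odd* integer (ties upward) so the receptive
   field is symmetric -- the raw formula yields even values for some $C$
   (e.g. $C = 128 \to 4$), and odd kernels are standard ECA practice.
   A sigmoid gate rescales each channel; the gates are retained because
   the analysis module turns them into per-band contribution shares.
6. **Classifier.** The four reweighted stacks are flattened
   (band-major), passed through dropout (rate 0.4, the midpoint of the
   0.3--0.5 range, training mode only) and a linear softmax layer. The
   loss is the negative log-likelihood plus $\lambda_{L2}\|\theta\|_2^2$
   over weights (biases excluded); $\lambda_{L2}$ is unspecified
   upstream and defaults to $10^{-4}$. A zero predicted probability is
   clamped at $10^{-12}$ before the logarithm.

Trials of different lengths (15 frames for listen, 20 for recall) are
handled natively: $\alpha$ is computed over whatever $T$ arrives, and all
downstream shapes are $T$-free.

### Initialization

Weight matrices use LeCun-normal initialization (the standard companion
of SELU); biases and the classifier weights start at zero, so the initial
class probabilities are exactly uniform. The spatial-attention
projections are the one place where scale matters qualitatively: the
attention scores reduce to $\langle w_G, w_F\rangle\, x_i x_p$ plus
row-constant terms, so if the inner product is near zero the softmax is
near uniform and every recalibrated frame collapses to its mean,
destroying the spatial structure the rest of the network needs. The
package therefore draws both projections randomly but corrects $w_F$
along $w_G$ so the initial score temperature $\langle w_G, w_F\rangle$ is
exactly 2, a value at which the attention differentiates DE-scale inputs
from the first step. Without this correction a fraction of seeds starts
in the collapsed regime and the 50-epoch budget is not enough to escape
it.

## Training protocol

Each subject gets a fresh model (subject-dependent training). Adam
(moment coefficients 0.9/0.999) minimizes the regularized NLL for 50
epochs at batch size 32. The learning rate starts at $10^{-4}$, drops to
$5\times10^{-5}$ when the recognition rate first reaches 70% and to
$10^{-5}$ at 85%, and never increases. The recognition rate that drives
the schedule is the *minimum* of training accuracy and the accuracy on a
stratified 10% held-out validation split: the held-out part guards
against triggering on memorization, while the training part guards
against triggering on validation noise -- with 160-trial datasets the
validation split holds only 14 trials, and a single lucky epoch at 85%+
would otherwise collapse the rate to $10^{-5}$ while the model is still
at chance (we observed exactly this failure in two of ten CV folds before
adopting the minimum).

Cross-validation is stratified ten-fold *at the trial level* -- windows
within a trial are strongly dependent, and window slicing is known to
inflate accuracy estimates for slow cognitive states -- with a fresh
model and a fold-derived seed per fold. Reports carry per-fold confusion
counts, accuracy/precision/specificity (undefined ratios surface as NaN
with a warning, not as silent zeros), pooled ROC points, and both
aggregation conventions (mean of fold metrics and pooled counts), since
either convention is defensible for the headline number.

## The synthetic study conditions

The recorded dataset behind this design is private, so the package ships
a generator whose defaults *are* the study conditions used by the test
suite and the acceptance script: 80 trials per class (160 total), 128 Hz,
15 s listen / 20 s recall epochs, 1/f background (exponent 1), band-limited
oscillatory components with per-trial Gaussian amplitude variability
(sd 0.1), broadband RMS of 20 uV, and a class effect planted as a
multiplicative power ratio of 3 in the gamma band at FP1/FPZ/O1/OZ/O2 --
frontal and occipital sites chosen to mirror the regions the recall state
is expected to engage. Signals are synthesized in the frequency domain
(random-phase spectra shaped by the envelope, i.e. sinusoid mixtures),
which makes the planted effect exact: multiplying the planted band's
spectral amplitude by $\sqrt{3}$ multiplies its power by 3 and shifts the
band DE by exactly $\ln(3)/2 \approx 0.55$ nats. With effect size 1 the
two classes are drawn from the same distribution apart from their
duration, giving a clean chance-level null. Optional 50 Hz line
interference exists solely to exercise the notch.

What the generator does **not** emulate: ocular/muscular artifacts,
volume conduction and the resulting inter-channel correlation structure,
cortical source geometry, non-stationarity within a trial, or
inter-subject variability. Passing the recovery simulations therefore
demonstrates that the implementation is correct and the method behaves as
designed under its own assumptions -- not that the reported real-data
accuracies transfer.

Simulation sizes were chosen to keep the full suite comfortably on one
CPU: the recovery and null cross-validations use 160 trials at a reduced
model width (embedding 4, filters 8/16/32); the Monte-Carlo calibrations
use 25--60 trials per run, 2000 permutations per screen, and 400--500
surrogates per connectivity null. The full-width model is the default for
interactive use.

## Post-hoc analyses

* **Attention topomap** -- the per-frame attention column masses (how
  much each grid position is attended to), aggregated with the
  $\alpha$ weights, averaged over trials and bands, min--max normalized
  over the occupied cells and thresholded; electrodes are ranked by
  normalized importance. The aggregation rule (column mass under
  $\alpha$-weighting) is this package's choice; the upstream description
  never pins down how a per-electrode scalar is formed from the attention
  tensors.
* **Band contributions** -- mean ECA gate mass per band, normalized to a
  simplex over the four bands.
* **SSAM--time correlation** -- Pearson correlation between each 2 s
  frame (occupied cells) and the steady-state map, with a display
  threshold of 0.6 by default; the threshold is a parameter because the
  source material uses both 0.6 and 0.5 in different places. Raw values
  are always retained; zero-variance frames are recorded as missing.
* **Connectivity** -- per band, Pearson correlation between all electrode
  pairs' concatenated DE series, with p-values from circular-shift
  surrogates (each channel independently rotated in time), which preserve
  each channel's autocorrelation while destroying cross-channel
  alignment. Per-band frames are the primary output; a band-averaged
  variant is also reported.
* **Significance screen** -- per electrode x band, a two-sample
  permutation test (10000 label permutations by default) on the
  difference of class means of trial-averaged DE. The permutation test is
  chosen because it is distribution-free and defensible at about eight
  trials per class. Flags use raw p-values at the 0.05 level -- the
  screening convention of the tables this mirrors -- and a
  Benjamini--Hochberg column is emitted alongside for readers who want
  the corrected view.

## Numerical and degenerate-input conventions

Logarithms are natural throughout (the DE derivation fixes the base).
Softmaxes subtract the row maximum before exponentiation. Constant
windows raise an error rather than returning $-\infty$; constant
channels yield missing correlation rows; an empty frame sequence, a
single-class dataset, and mismatched shapes all raise early errors naming
the offending quantity. Checkpoints embed the model configuration and a
format version, and the loader refuses foreign versions.

## Known limitations

The training kernel is single-threaded by design (determinism under a
seed beats wall-clock here). EDF support covers the plain 16-bit profile
(no EDF+ annotations). The ECA kernel is shared across the four band
groups -- the parameter list defines one 1-D kernel -- so band
specialization at the fusion stage comes only from the gates' inputs. The
attention-collapse analysis above also exposes a structural property
worth knowing: with scalar per-cell inputs, the spatial attention is an
exactly two-parameter family per frame (an effective temperature and a
key offset), so its expressiveness is far below what the $81\times81$
attention tensor suggests; the package implements the full parametrization
faithfully but the reader should not over-interpret attention maps as
81-dimensional objects.
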