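---
title: "Spectral subband neural transform coding: model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spectral subband neural transform coding: model and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sbpnn)
```

## The codec in one page

`sbpnn` compresses 8-bit grayscale biomedical images by composing three
stages, each of which can be used on its own:

1. **Cosimilar pair-value coding** (`encode_pairs()`). The image matrix is
   scanned in row-major raster order and each maximal run of equal values
   is collapsed to a pair \((U_i, V_i)\) — the value and its occurrence
   count. This is run-length coding; on medical images with large
   homogeneous regions (flat backgrounds, organ interiors) it removes most
   of the spatial redundancy. The pairs can be flattened to the interleaved
   sequence \(S = U_1, V_1, U_2, V_2, \dots\) (`flatten()`), and both steps
   invert exactly.
2. **A bottleneck neural transform coder** (`init_weights_hebbian()`,
   `train()`, `nn_encode()`, `nn_decode()`). The run-value stream is cut
   into chunks \(x \in \mathbb{R}^n\) (default \(n = 16\)), normalized into
   \([-1, 1]\), and passed through a single hidden layer of \(k < n\) units
   (default \(k = n/2\)): hidden code \(h = \tanh(W_{\mathrm{enc}} x)\),
   linear output \(y = W_{\mathrm{dec}} h\). The \(k\)-vector \(h\),
   quantized to 8 bits per unit, is the stored representation; \(k\) is the
   rate knob. The encoder is initialized from the chunk Gram matrix
   \(\sum_i x_i x_i^{\top}\): its top-\(k\) unit eigenvectors form
   \(W_{\mathrm{enc}}\) (the decoder starts as its transpose), i.e. the
   classical autoassociative/PCA construction, and both weight sets are then
   refined by least-mean-square backpropagation with the conventional
   stopping rule (error goal 0.1, at most 50 epochs).
3. **Pyramidal wavelet decomposition** (`decompose()`, `reconstruct()`),
   used by the *spectral* mode. One level of a 2-D orthonormal DWT splits
   the image into four planes: horizontal, vertical and diagonal detail
   plus the approximate (low-pass) plane; the filter bank recurses on the
   approximate plane for deeper pyramids. Detail planes are quantized with
   a uniform scalar step (default 1.0), the approximate plane with a finer
   step (default 0.5, because it carries most of the signal energy), and
   each plane is then coded by stages 1–2 with its own network model.

Three top-level modes (`codec_config()`):

* `lossless` — stage 1 only, pairs stored raw; decompression is bit-exact.
* `direct` — stages 1–2 on raw pixels.
* `spectral` — stage 3 followed by stages 1–2 per subband (the proposed
  codec).

The container (`serialize_artifact()`) is a little-endian binary format
(magic `SBPN`) whose byte length defines "compressed size" in every rate
metric; the header records mode, dims, levels, wavelet and per-stream
coding parameters, and the payload holds run counts (LEB128-style
varints), run values (zigzag varints, lossless mode), 8-bit hidden codes
and 32-bit float decode weights. Decompression needs nothing but the
container.

## Design decisions in the lossy path

Several aspects of this architecture are underdetermined, and the package
resolves them as follows.

**Run counts are stored exactly; the network codes only run values.** A
network that lossily reconstructs the interleaved sequence \(S\) would
also perturb the counts, and the decoded stream would no longer sum to
\(m \times n\) — there is no way to rebuild an image of the right size
from it. We therefore split \(S\): the count positions are stored exactly
as varints (they are cheap — one to three bytes per run), and the
bottleneck network codes the value positions. Run geometry survives lossy
coding; all loss is confined to run values.

**The training goal is interpreted on the coded-value scale.** The stop
rule "error \(\le 0.1\) or 50 epochs" is meaningful only once the scale of
the error is fixed. On the normalized \([-1,1]\) scale, an MSE of 0.1
corresponds to a root-mean-square error of roughly 40 intensity levels —
training would stop after a single epoch with visibly degraded output. The
pipeline therefore treats the goal as an MSE in intensity (coded-value)
units and passes `goal / s_max^2` to the trainer, so that easy streams
stop early and hard streams train for the full 50 epochs. `train()` itself
is scale-agnostic: it stops as soon as the MSE of the chunks it was given
reaches the goal it was given.

**Normalization targets the sigmoid's linear range.** All coded value
streams use the signed rule \(z = x / s_{\max}\), with
\(s_{\max} = \max |x|\) inflated by the largest hidden pre-activation of
the initialized encoder (the min–max extraction step). With unit-norm
eigenvector rows, pre-activations can reach \(\sqrt{n} \approx 4\), deep in
tanh saturation, which cripples both the initial fit and the gradient;
after rescaling they start within \([-1, 1]\), where tanh is close to
linear, while the hidden codes still span most of the fixed 8-bit
\([-1, 1]\) storage quantizer. This is the same motivation as
Nguyen–Widrow initialization in classical feed-forward practice.
`chunk_and_normalize()` keeps the symmetric offset map
\(x \mapsto 2x/s_{\max} - 1\) as its default for nonnegative streams; the
pipeline simply opts into the signed rule.

**Training dynamics.** Each epoch takes one backtracking gradient step on
the encoder followed by an exact least-squares refit of the decoder — both
are descent steps on the same least-mean-square objective, so the error
history is non-increasing and the returned model is never worse than the
initialization. Training is full-batch and free of randomness: a fixed
seed (indeed any seed) gives bit-identical weights.

**Decoded values** are denormalized, clipped to the value range recorded
in the stream header, and rounded to integers before the run expansion;
decompressed pixels are finally clipped to \([0, 255]\).

## Parameters

| Parameter | Default | Meaning |
|---|---|---|
| `mode` | `"spectral"` | `lossless`, `direct` or `spectral` |
| `wavelet` | `"haar"` | orthonormal filter pair; `"db2"` (Daubechies-4) also built in |
| `levels` | 1 | pyramid depth; 1 gives exactly the four planes |
| `q_detail`, `q_approx` | 1.0, 0.5 | uniform quantizer steps per subband class |
| `chunk_n` | 16 | network input length \(n\) |
| `k` | 8 | hidden size; the main rate/quality knob |
| `goal` | 0.1 | training stop threshold (intensity-scale MSE in the pipeline) |
| `max_epochs` | 50 | training epoch cap |
| `seed` | 1 | recorded in models; the pipeline is deterministic regardless |

The default wavelet is Haar with one level: the minimal configuration that
yields the four-plane decomposition, and the usual choice in neural
subband coders of this family. Odd image dimensions are handled by
half-sample replication of the final row/column before each filtering
stage, with original dims recorded so reconstruction crops exactly; the
transform is otherwise periodized, so reconstruction is exact to floating
precision at any depth.

## The phantom generator

`generate_phantom()` emulates the regime this codec targets — large
homogeneous regions, smooth intensity gradients, additive noise — without
modeling any acquisition physics: a flat background plus a few quantized
elliptical or rectangular regions whose total area tracks
`1 - background_fraction`, an optional horizontal intensity ramp, and
optional iid Gaussian noise added before the single final rounding step.
Region layout depends only on the seed and region sizes scale with the
foreground budget, so sweeping `background_fraction` under one seed gives
nested layouts with monotonically increasing run-length redundancy — the
controlled input used by the compression-ratio tests.

What passing tests on phantoms do **not** show: real radiographs have
spatially *correlated* texture and acquisition noise, which a wavelet
decomposition concentrates into few coefficients. The phantoms' iid noise
is instead spectrally flat — equally present in every subband — which is
the least favorable content for subband coding. Results on phantoms
therefore bound the codec's behavior on structure and on worst-case noise,
not its behavior on real tissue texture. Relatedly, the evaluation
harness's matched-rate comparison between the spectral and the direct
codec (recomputed by `compare_modes()` and the acceptance script on every
run) shows the direct coder holding a small PSNR edge on this phantom
family; on content whose detail bands quantize to near-zero at negligible
cost — the classical subband-coding premise — the balance shifts toward
the spectral path.

## Numerical choices

* Quantization rounds half away from zero, so coefficient signs are
  treated symmetrically; `dequantize(quantize(x, s), s)` is within
  \(s/2\) elementwise.
* Eigenvector signs follow a fixed convention (largest-magnitude entry
  positive), making initialization reproducible across platforms.
* The decoder refit adds a relative ridge of \(10^{-10}\) to the hidden
  Gram matrix, so degenerate (rank-deficient, e.g. constant) streams are
  handled without special cases.
* Degenerate inputs: single-pixel images, single-run streams, all-zero
  subbands and rank-deficient chunk sets all flow through the ordinary
  paths; tests pin each.
* Problem sizes in the test and acceptance harnesses (50 lossless round
  trips up to 512 px, 100 pyramid reconstructions, 1000 pair-coder
  inversions, a 20-phantom 256 px comparison suite) were chosen to
  exercise every size regime the codec targets while keeping a full run
  within a coffee break.

## Known limitations

* 8-bit grayscale only; deeper bit depths are rejected rather than
  rescaled, and color is out of scope.
* The bottleneck coder is a rank-\(k\) transform on fixed-phase chunks:
  streams whose chunks contain intensity edges at arbitrary offsets are
  not low-rank, which caps lossy quality on edge-dense content
  independently of training.
* Run counts are side information stored exactly; on noise-dominated
  images runs collapse to length 1 and the count block roughly doubles the
  rate — lossy compression ratios below 1 are possible there by design
  rather than silently degrading geometry.
* No entropy coder sits behind the pair stream; adding one would improve
  every mode's rate at the cost of the format's simplicity.
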