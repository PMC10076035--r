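---
title: "Prioritized replay from experience strength, spatial structure and inhibition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Prioritized replay from experience strength, spatial structure and inhibition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sfma)
```

## The model

Hippocampal replay — the sequential reactivation of place-cell ensembles
during rest and sleep — is modeled here as stochastic, prioritized
reactivation of stored *experience tuples* $e = (s, a, r, s')$ in discrete
grid worlds with the four cardinal actions. An agent's interactions populate
a memory that holds one experience per (state, action) pair, and three
quantities drive which experience is reactivated next, given the most
recently reactivated experience $e_t$:

$$R(e \mid e_t) = C(e)\, D(e \mid e_t)\, [1 - I(e)]$$

* **Experience strength** $C(e)$ counts how often a transition was
  experienced ($C \leftarrow C + 1$ per visit) and is additionally raised by
  encountered rewards, $C(e) \leftarrow C(e) + r\,D(e \mid e_r)$, where the
  spread is weighted by each experience's similarity to the *rewarded
  location* (the landing state of the reward-delivering experience $e_r$).
  The `reward_modulation` multiplier scales this second term; raising it is
  equivalent to raising the reward magnitude.
* **Experience similarity** $D(e \mid e_t)$ is structure-aware: it is read
  from the Default Representation (DR), $D = (X - \gamma_{DR} T)^{-1}$, the
  discounted expected state occupancy under a uniform default policy with
  transition matrix $T$ (wall and barrier bumps are self-transitions, so $T$
  is row-stochastic). Because barriers lengthen the paths between states,
  the DR respects environmental structure where a Euclidean kernel
  $D(e_i \mid e_j)=\exp(-\lVert s_i - s_j\rVert)$ (implemented as the
  control model) does not. In the **default mode** the current state of
  $e_t$ is compared with the current states of all stored experiences; in
  the **reverse mode** with their next states, which chains reactivations
  backward along experienced paths.
* **Inhibition of return** $I(e) \in [0,1]$ is set to 1 for every experience
  sharing the source state of a just-reactivated experience and decays each
  replay step by $\lambda$. It is what turns the winner-take-most selection
  into extended sequences, and it is reset at the start of every epoch.

Reactivation probabilities come from a customized softmax over
max-normalized ratings,
$P_i = (e^{\beta_M \hat R_i} - 1) / \sum_j (e^{\beta_M \hat R_j} - 1)$,
so that zero-rated experiences receive exactly zero probability. An epoch
stops after a configured number of steps or when all ratings fall below
$\theta$. Awake (online) replay is initiated at the agent's position
(experience drawn proportional to strength among that state's experiences);
sleep (offline) replay draws any experience with probability
$C(e)/\sum C$. In the **dynamic mode** each epoch is generated in the
reverse mode with probability $1/(1+e^{-(5\Delta - 2)})$, where $\Delta$
accumulates absolute TD errors since the last trial.

Replayed experiences train a tabular Q-learner with the ordinary backup
$Q(s,a) \leftarrow Q(s,a) + \eta\,[r + \gamma \max_{a'} Q(s',a') - Q(s,a)]$.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| $\gamma_{DR}$ | 0.1 | DR discount; sets the spatial reach of similarity (unitless, in $[0,1)$) |
| $\beta_M$ | 9 | softmax inverse temperature on max-normalized ratings |
| $\lambda$ | 0.9 | per-step inhibition decay |
| $\theta$ | $10^{-6}$ | stop threshold on the maximum rating |
| $\eta$, $\gamma$ | 0.9, 0.99 | Q-learning rate and discount |
| `reward_modulation` | 1 | reward weighting of strength updates |
| $\varepsilon$ | 0.1 | behavioral exploration (the exploration policy is not fixed by the modeled experiments; $\varepsilon$-greedy with masking of self-transitions is used for training, softmax with a stated $\beta$ for evaluation phases) |

## Design choices where the design was genuinely open

* **Rating normalization.** The softmax operates on ratings divided by their
  maximum. This makes $\beta_M$ comparable across environments and strength
  scales; it is the single most behavior-sensitive choice and is exposed as
  `normalization = "max"` / `"sum"` in `replay_config()`.
* **Dynamic-mode sigmoid.** The reverse-mode probability is the *increasing*
  sigmoid $1/(1+e^{-(5\Delta-2)})$: the probability of reverse replay must
  grow with accumulated TD error; the opposite sign convention would give
  $P(\text{reverse} \mid \Delta{=}0) \approx 0.88$ and shrink with error.
* **Initial inhibition.** Inhibition applies to every reactivated
  experience, including the initiating one; otherwise the first transition
  of each epoch would almost surely stutter on the initiation state.
* **Reward-spread center.** The strength spread on reward is centered on
  the rewarded location $s'(e_r)$ rather than on the source state of
  $e_r$. Centering one state early systematically over-strengthens the
  penultimate state and makes it, not the goal, the most reactivated state
  under strong reward modulation — contradicting the phenomenon the
  mechanism exists to produce.
* **DR orientation.** Grid worlds under the uniform policy have symmetric
  $T$ (exactly one action each way between adjacent free cells), so
  $(X-\gamma_{DR}T)^{-1}$ is symmetric and row/column orientation is
  immaterial; the implementation stores `D = solve(I - gamma * T)` and all
  lookups read `D[s_cmp, s(e_t)]`.
* **Online initiation.** The initiating action at the agent's position is
  drawn proportional to strength among that state's four experiences,
  consistent with the strength-proportional philosophy of offline
  initiation.
* **Barriers as transition pairs.** Barriers are stored as blocked state
  pairs, not cell attributes, so the same machinery expresses T-maze blocks
  and the environment switches of the adaptive-replay protocol, and the DR
  can be carried across structural changes by a Woodbury rank-$k$
  correction confined to the affected source states
  (`apply_barrier_update()`, verified against the direct inverse to
  $10^{-8}$).

## The synthetic protocols and what they emulate

All data in this package are generated by the protocol runners; there is no
external data. The runners emulate the behavioral schedules of the modeled
experiments: scripted stem laps and visual cueing in a blocked T-maze
(`run_preplay()`), stereotyped lap running on a figure-eight track
(`run_shortcut()`), successive barrier rearrangements (`run_adaptive()`),
goal-directed learning with begin/end/offline replay (`run_navigation()`,
`run_reward_modulation()`), pre-exposure plus a single aversive event
(`run_aversive()`), and free diffusion of replay in a large open field
(`run_random_walk()`).

Two idealizations matter when reading test results. First, behavior is
either scripted or $\varepsilon$-greedy on a tabular Q-function; real
rodents' running statistics are richer, so passing tests show that the
*replay mechanism* produces the reported phenomena under the stated
schedules, not that the behavioral model is realistic. Second, grid worlds
quantize space; quantities like the diffusion exponent are recovered from
lattice walks, which is also how the original analyses treated decoded
positions.

### Preplay accounting

The cue phase raises arm experience strengths by the increase that the same
amount of physical running as the run phase (ten out-and-back laps) would
have produced, scaled by `attention_strength * asymmetry` for the cued arm
(including the reward-spread increments from the visible arm reward) and by
`attention_strength * (1 - asymmetry)` for the uncued arm (visits only; it
holds no reward). The stored memory reflects the *observable* maze
structure (junction-to-arm transitions exist), while the DR folds the
barrier in, so cross-barrier similarities are exactly zero: preplay can
never flow between stem and arms, but preplay-trained Q-values can express
the cued-arm choice once the barrier is removed. Because each trace is
confined to one maze component, stem-component traces are counted as stem
replays directly; arm-component traces count as cued/uncued preplay when
they match an arm template with at most two mismatches. Before preplay
generation the stored reward fields are reduced to the visible cued-arm
reward: the run-phase stem-end rewards shaped the strengths but, if left in
place, they create positive value cycles that saturate the Q-function and
erase the arm preference.

### Shortcut geometry

Corner templates are five-cell paths with the corner cell (apex) at the
center position; a shortcut requires one corner matched backward and the
complementary corner matched forward with 8±2 replayed states strictly
between the two apexes. On the shipped 11×7 track an exact top- or
bottom-rail crossing places 9 states between the apexes. The wall layouts
of the figure-eight and labyrinth fixtures are approximations validated by
connectivity and lap-length checks (the originals exist only as figures).

## Numerical choices

Linear solves replace explicit inversion for large state spaces, with the
dense inverse retained as the test oracle. Ratings are clamped at zero to
absorb $10^{-15}$-scale negatives left by low-rank DR updates. The
sequential sampler draws by inverse CDF on the cumulative weights, which
preserves exact zeros. Replay is reproducible: one seeded RNG drives mode
choice, initiation and sampling in that order within each epoch. Greedy
ties in action selection are broken uniformly; pairs of consecutively
replayed experiences that satisfy both the forward and the reverse
directionality condition (immediate bounces) are counted as unordered.
Degenerate inputs are defined: a 1×1 world has four self-transitions and
$T = [1]$; replay from a state whose experiences all have zero strength is
an initiation failure; an epoch whose ratings all fall below $\theta$ stops
with `stop_reason = "below_threshold"`.

## Problem sizes used by the test suite

The packaged checks run reduced presets chosen to exercise the same
mechanisms at smaller cost: a 50×50 diffusion arena (50 replays × 500
steps per cell) with the $(\gamma_{DR}, \lambda)$ grid subsampled to its
extremes and midpoints $\{0.01, 0.5, 0.9\} \times \{0, 0.5, 0.9\}$; ten
repetitions of the reward-modulation protocol and thirty of the aversive
protocol. The full-scale settings (100×100 arena, full 10×10 parameter
grid, 100 repetitions) are plain arguments to the same runners.

## Known limitations

The model does not decide *when* replay occurs or how much of it; epoch
counts and lengths are protocol inputs. Strength conflates experience and
reward frequency in one scalar; motivational state and behavioral recency
are outside the model. The figure-eight and labyrinth layouts are
approximate reconstructions. Learning-curve comparisons depend on the
unspecified exploration policy; with Dyna-style online updates all variants
eventually converge on small environments, so variant differences
concentrate in mid-training rather than in asymptotic latency.
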