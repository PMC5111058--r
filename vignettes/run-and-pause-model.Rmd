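---
title: "The run-and-pause motility model: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The run-and-pause motility model: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(runpause)
```

## The model

Intracellular cargo transport by motor proteins is intermittent: phases of
active, roughly ballistic motion along cytoskeletal filaments alternate with
pauses in which the motor stalls, or detaches and stays put, before resuming.
`runpause` implements the minimal Markovian description of this behaviour: a
discrete-time walker with two motility states, switching motion → pause with
a constant per-step probability $\kappa_w$ and pause → motion with
$\kappa_m$. Constant switching probabilities imply geometric (discrete
exponential) residence times with means $1/\kappa_w$ and $1/\kappa_m$ steps
— consistent with measured active-lifetime distributions of cargoes on the
cytoskeleton — and make the state sequence a two-state Markov chain with
relaxation factor $r = 1 - \kappa_w - \kappa_m$ and stationary motion
occupancy $s = \kappa_m / (\kappa_m + \kappa_w)$.

Two geometries are covered:

* **Single filament.** Motion is unidirectional with i.i.d. step lengths
  $\ell$. The position is $x(n) = \sum_{i=1}^n \sigma_i \ell_i$ with
  $\sigma_i \in \{0, 1\}$ the motion indicator, and the exact ensemble MSD
  is the correlation sum
  $$\langle x^2(n)\rangle = \langle \ell^2\rangle \sum_i P_i
    + 2\langle \ell\rangle^2 \sum_{i<j} P_i\, G(j-i),$$
  with $P_i = q_m(i) = s + (q_{m0}-s) r^i$ the motion occupancy and
  $G(k) = s + (1-s) r^k$ the $k$-step motion→motion return probability.

* **Filament network.** At the coarse-grained level of junction-to-junction
  moves in the plane, the network geometry enters only through the
  step-length distribution (heterogeneity
  $\lambda = \langle\ell^2\rangle/\langle\ell\rangle^2 \ge 1$) and the
  turn-angle distribution $R(\varphi)$ at junctions (anisotropy
  $\hat R = E[\cos\varphi]$). A motor with processivity $p$ keeps its
  filament at a junction with probability $p$ and otherwise turns by a draw
  from $R$; every motion step therefore multiplies the directional
  correlation by the **effective persistence** $A = p + (1-p)\hat R$, the
  only combination of $p$ and $\hat R$ the displacement moments depend on.
  The MSD is the same correlation sum with $G$ replaced by $g(k)$, the
  motion entry of $M^k e_1$ for the $A$-weighted transfer matrix
  $$M = \begin{pmatrix} A(1-\kappa_w) & A\kappa_m \\
                        \kappa_w & 1-\kappa_m \end{pmatrix}.$$
  Summing the geometric tail gives
  $\sum_{k\ge1} g(k) = A/(1-A)$ independent of the rates, whence the
  asymptotic per-step MSD slope $s\,\langle\ell\rangle^2\,\Gamma(\lambda,A)$
  with $\Gamma = \lambda + 2A/(1-A)$, and with the physical tick
  $\langle\ell\rangle/v$ the diffusion constant
  $D_\infty = s\, v\, \langle\ell\rangle\, \Gamma(\lambda, A)/4$.

The running anomalous exponent $\alpha(n)$ is the local log-log slope of the
MSD between consecutive steps; the crossover step $n_c$ to the asymptotic
exponent (2 on a filament, 1 on a network) is where
$|\alpha - \alpha_\infty|$ drops below a threshold $\varepsilon$ and stays
below it.

## Conventions that fix the numbers

Several discrete-time conventions are genuinely open; the package fixes them
as follows, and the enumeration oracle (`enumerate_msd_single()`,
`enumerate_msd_network()`) pins each one testably.

* **Step ordering.** The state at step $n$ results from applying the
  transition kernel to the state at $n-1$, and the displacement at step $n$
  uses the post-transition state; no step is taken at $n = 0$. Consequences:
  a sure motion start with $\kappa_w = 1$ never moves, and an all-waiting
  start with $\kappa_w = 0$ has the occupancy cascade
  $P_i = 1 - (1-\kappa_m)^i$.
* **Direction bookkeeping (network).** The direction update (keep with
  probability $p$, else turn) happens at *every* motion step, including the
  first; waits do **not** decorrelate direction — the motor rests at a
  junction on its filament. This makes $A = 1$ reduce exactly to the
  single-filament engine, which is tested to full precision.
* **Heterogeneity.** $\lambda = \langle\ell^2\rangle/\langle\ell\rangle^2$,
  so $\lambda = 1$ iff the step length is constant; the exponential
  (mesh-spacing) model has $\lambda = 2$.
* **Turn symmetry.** $R$ must be symmetric about zero ($E[\sin\varphi]=0$);
  asymmetric distributions are rejected rather than silently symmetrised,
  because the planar moment algebra assumes the sine moment vanishes.
* **Square-lattice turns.** "Single-state motion on a square lattice" is
  realised as turns uniform on $\{0°, +90°, -90°\}$ (no direct reversal),
  giving $\hat R = 1/3$ and the non-processive initial exponent
  $\log_2(8/3) \approx 1.415$; this is the unique symmetric lattice turn set
  reproducing that value.
* **Crossover rule.** $n_c$ is one past the *last* computed step with
  $|\alpha - \alpha_\infty| \ge \varepsilon$ (sustained crossing), not the
  first crossing: waiting-start ensembles overshoot the ballistic exponent
  and re-cross it, and the sustained rule is the disambiguation that is also
  correct for monotone tails. Cells of a phase scan that have not converged
  within the horizon are flagged and reported as lower bounds, never
  extrapolated.
* **Physical time.** Waiting steps consume the same tick as motion steps
  (the master equations are synchronous), and the tick is the segment
  traversal time $\langle\ell\rangle/v$ — 8 ms for an 8 nm stepper at
  1 µm/s, 0.1 s per 100 nm mesh crossing at the same speed.
  `steps_to_time()` / `time_to_steps()` apply exactly this map and nothing
  more.

## Numerical choices

The correlation sums are evaluated in $O(n)$ by linear recurrences, not by
closed-form geometric sums: the inner sum obeys
$U(j) = r\,(U(j-1) + P_{j-1})$ (evaluated by `stats::filter(method =
"recursive")` at C speed) and its network analogue is the two-vector
recursion $V(j) = M\,(V(j-1) + P_{j-1}e_1)$. The recurrences are
algebraically exact, cancellation-free at $|r| \to 1$, and handle the
boundary rates $0$ and $1$ without special cases; the frozen chain
$\kappa_w = \kappa_m = 0$ is folded in via $s = 1$, $r = 1$, which
reproduces $q_m \equiv q_{m0}$ and a unit return probability. Against the
$2^n$ enumeration oracle both engines agree to $\sim 10^{-14}$ absolute over
randomized sweeps that include the boundaries.

Degenerate inputs are errors, not guesses: a zero MSD at step 1 makes the
initial exponent undefined ($\kappa_w = 1$ with a sure motion start);
$A = 1$ makes $D_\infty$ diverge; $\kappa_w = \kappa_m = 0$ has no
stationary state. The continuous-time waiting-start MSD
$v^2(t^2 - 2t/\kappa + 2/\kappa^2 - 2e^{-\kappa t}/\kappa^2)$ cancels
catastrophically below $t \sim 10^{-4}$ in double precision, where its value
is $\sim v^2\kappa t^3/3 \approx 10^{-13}$; its small-$t$ slope (the leading
power 3) is therefore evaluated at $t \sim 10^{-3}$, where the slope
$3 - \kappa t/4$ has converged to well within every tolerance used.

## The simulator: what it does and does not emulate

`simulate_single()` and `simulate_network()` advance the full ensemble in
vectorised sweeps from one seeded generator; identical
`(seed, parameters, n_walkers)` give identical output. The default ensemble
of $10^6$ walkers matches the scale used for the reference curves; the test
suite uses $10^4$–$10^5$ walkers with 3-standard-error gates, and records on
a log-spaced step grid (~60 points) by default. The recorded table carries
the MSD, its standard error, and the motion-state fraction (checked against
the occupancy closed form at binomial precision).

The simulator emulates exactly the model above — Markovian switching,
i.i.d. step lengths, per-motion-step turning — and nothing else. Passing
tests therefore say nothing about features of real motor data the model
abstracts away: motor–motor interactions and crowding, displacement during
detached phases (run-and-tumble with a mobile passive state),
non-Markovian residence times, chemomechanical stepping detail, or explicit
network geometry with spatially correlated junctions. The network is
*dynamic* in the weak sense that each junction presents a fresh draw of
$R(\varphi)$ and $f(\ell)$; quenched-disorder effects are outside the model
by construction.

## Parameters at a glance

| Parameter | Meaning | Range / default |
|---|---|---|
| $\kappa_w$ | motion → pause probability per step | $[0,1]$ |
| $\kappa_m$ | pause → motion probability per step | $[0,1]$ |
| $q_{m0}$ | probability of starting in motion | $[0,1]$, default 1 |
| $\langle\ell\rangle$ | mean step / segment length (model units) | $>0$, default 1 |
| $\lambda$ | $\langle\ell^2\rangle/\langle\ell\rangle^2$ | $\ge 1$; 1 constant, 2 exponential |
| $p$ | processivity at junctions | $[0,1]$, default 0 |
| $\hat R$ | $E[\cos\varphi]$ of the turn distribution | $[-1,1]$; 0 isotropic |
| $A$ | $p + (1-p)\hat R$, persistence per motion step | $[-1,1]$ |
| $\varepsilon$ | crossover threshold on $|\alpha-\alpha_\infty|$ | default $10^{-2}$ |
| $v$ | motor speed for unit conversion | $>0$ |

The default $\varepsilon = 10^{-2}$ follows the convention used for the
reference phase diagrams; conclusions are insensitive to its choice, which
can be re-checked by sweeping `epsilon` in `crossover_time()` or
`phase_scan()`.

## Known limitations

* **Near-stationary starts.** Starting below the stationary motion
  occupancy ($q_{m0} < s$) accelerates the ensemble as walkers are injected
  into ballistic motion, and for strongly sub-stationary starts (notably
  $q_{m0} = 0$) the running exponent exceeds 2. For $q_{m0}$ only marginally
  below $s$, however, the injection transient is too weak to push
  $\alpha$ above 2 (e.g. $\kappa_w = 0.1$, $\kappa_m = 0.001$,
  $q_{m0} = s/2$ peaks at $\alpha \approx 1.96$): the super-ballistic
  regime is a property of clearly unbalanced initial conditions, not of
  every sub-stationary start.
* **Pointwise Monte Carlo gates.** Because all recorded steps of one
  ensemble share walkers, their deviations from the exact MSD are strongly
  correlated: a single early fluctuation (e.g. a deficit of rare pause
  events at small $\kappa_w$) shifts the whole curve by a fraction of a
  standard error. Pointwise $3\sigma$ gates over many recorded steps should
  be read with this multiplicity in mind.
* **Crossover horizons.** $n_c$ grows like (prefactor ratio)/$\varepsilon$
  and exceeds any fixed horizon as $\kappa_m \to 0$ or $A \to 1$; scans
  report such cells as flagged lower bounds. The test suite uses horizons of
  $2\times10^4$ (scans) to $10^6$ (asymptotics) steps, chosen so that the
  asymptotic regime is genuinely reached for the parameter sets examined.
* **No inference.** The package generates model predictions; estimating
  $\kappa_w$, $\kappa_m$ or $A$ from experimental trajectories is out of
  scope.
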