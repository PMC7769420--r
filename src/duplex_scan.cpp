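#include <Rcpp.h>
#include <vector>
#include <map>
#include <array>
#include <string>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

// Base encoding: A=0 C=1 G=2 T=3, anything else (N) = -1.
static inline int base_code(char c) {
  switch (c) {
  case 'A': return 0;
  case 'C': return 1;
  case 'G': return 2;
  case 'T': return 3;
  default:  return -1;
  }
}

// Pair state of an sRNA base against the target base it sits opposite
// (target read on the mRNA sense strand, duplex antiparallel):
// 0 = Watson-Crick, 1 = G:U wobble, 2 = mismatch, -1 = undetermined (N).
static inline int pair_code(int s, int t) {
  if (s < 0 || t < 0) return -1;
  int sum = s + t;
  if (sum == 3) return 0;              // A:T, C:G
  if (sum == 5) return 1;              // G:T or T:G (G:U in RNA space)
  return 2;
}

struct Hit {
  int start, end;
  double pen;
  int nb, nmm;
  std::string states;                  // one char per sRNA position: W/G/M/b
  std::string bulges;                  // "S:pos:len;T:pos:len;..."
  std::vector<int> pairmap;            // per sRNA position: target pos or 0
};

// penalty, then bulge count, then mismatch count; strictly-better only
static inline bool better(double pen_a, int nb_a, int nmm_a,
                          double pen_b, int nb_b, int nmm_b) {
  if (pen_a < pen_b - 1e-9) return true;
  if (pen_a > pen_b + 1e-9) return false;
  if (nb_a != nb_b) return nb_a < nb_b;
  return nmm_a < nmm_b;
}

// Scan one sRNA against one transcript with a banded duplex-alignment DP.
//
// Alignment grammar: the full sRNA (positions 1..L from its 5' end) aligns
// antiparallel against a contiguous transcript segment [start, end], sRNA
// position 1 pairing the base at `end`. Up to max_bulges internal bulge
// events are allowed on either strand, each one or more contiguous unpaired
// nucleotides; sRNA positions 1 and L (and hence both segment boundaries)
// must be paired. Penalties: G:U wobble gu_pen; mismatch mm_seed inside
// [seed_start, seed_end] else mm_nonseed; bulge event bulge_pen plus
// bulge_ext per nucleotide beyond the first. Rejection: mismatch at a
// forbidden position; more than max_seed_mm mismatches (G:U excluded) in
// the seed; more than max_bulges events; penalty above max_score. Segments
// containing N are never scored or bulged across.
//
// One alignment is reported per segment start: minimum penalty, ties broken
// by fewer bulges, then fewer mismatches, then smallest end.
// [[Rcpp::export]]
List duplex_scan_cpp(std::string srna, std::string target,
                     double gu_pen, double mm_seed, double mm_nonseed,
                     double bulge_pen, double bulge_ext,
                     int max_seed_mm, int seed_start, int seed_end,
                     IntegerVector forbidden_pos,
                     int max_bulges, double max_score) {
  const int L = (int)srna.size();
  const int T = (int)target.size();

  std::vector<int> s(std::max(L, 1)), tg(std::max(T, 1));
  for (int i = 0; i < L; ++i) s[(size_t)i] = base_code(srna[(size_t)i]);
  for (int p = 0; p < T; ++p) tg[(size_t)p] = base_code(target[(size_t)p]);

  std::vector<bool> forb((size_t)L + 2, false);
  for (int k = 0; k < forbidden_pos.size(); ++k) {
    int fp = forbidden_pos[k];
    if (fp >= 1 && fp <= L) forb[(size_t)fp] = true;
  }

  // Band half-width: the largest one-sided total of bulged nucleotides any
  // alignment within the score budget can carry.
  int B = 0;
  for (int nb = 1; nb <= max_bulges; ++nb) {
    double left = max_score - nb * bulge_pen;
    if (left < -1e-9) break;
    int tot = nb + (bulge_ext > 1e-12 ? (int)std::floor(left / bulge_ext + 1e-9) : 10);
    if (tot > B) B = tot;
  }
  if (B > 10) B = 10;
  const int W  = 2 * B + 1;
  const int NB = max_bulges + 1;
  const int NS = max_seed_mm + 1;
  const int NG = 3;                    // 0 paired, 1 in-sRNA-gap, 2 in-target-gap
  const size_t ncell = (size_t)(L + 1) * W * NG * NB * NS;
  const double INF = 1e30;

  std::vector<double> val(ncell, INF);
  std::vector<int> nmm(ncell), ptype(ncell), pprev(ncell);
  std::vector<int> stamp(ncell, -1);           // lazy per-end reset
  std::vector<char> layer_live((size_t)L + 1);
  int cur = -1;

  auto idx = [&](int i, int d, int g, int nb, int ns) -> size_t {
    return (((size_t)i * W + (size_t)(d + B)) * NG + (size_t)g)
             * (size_t)(NB * NS) + (size_t)nb * NS + (size_t)ns;
  };
  auto relax = [&](int li, size_t c2, double v2, int m2, int tt, size_t from) {
    if (stamp[c2] != cur || v2 < val[c2] - 1e-9 ||
        (v2 < val[c2] + 1e-9 && m2 < nmm[c2])) {
      stamp[c2] = cur;
      val[c2] = v2; nmm[c2] = m2; ptype[c2] = tt; pprev[c2] = (int)from;
      layer_live[(size_t)li] = 1;
    }
  };

  std::map<int, Hit> winners;

  if (L >= 2) for (int e = L; e <= T; ++e) {   // e = target_end
    ++cur;
    std::fill(layer_live.begin(), layer_live.end(), 0);

    // sRNA position 1 must pair the base at e
    {
      int pc = pair_code(s[0], tg[(size_t)(e - 1)]);
      if (pc < 0) continue;
      double p0 = 0.0; int m0 = 0, ns0 = 0;
      bool ok = true;
      if (pc == 1) p0 = gu_pen;
      else if (pc == 2) {
        if (forb[1]) ok = false;
        m0 = 1;
        if (1 >= seed_start && 1 <= seed_end) {
          ns0 = 1; if (ns0 >= NS) ok = false; p0 = mm_seed;
        } else p0 = mm_nonseed;
      }
      if (ok && p0 <= max_score + 1e-9) {
        size_t c = idx(1, 1 - 1, 0, 0, ns0);   // t = 1, d = t - i = 0
        stamp[c] = cur;
        val[c] = p0; nmm[c] = m0; ptype[c] = 0; pprev[c] = -1;
        layer_live[1] = 1;
      }
    }

    for (int i = 1; i <= L; ++i) {
      if (!layer_live[(size_t)i]) break;   // deeper layers are unreachable
      // target-side gap transitions stay in layer i; ascending d so that
      // gap extensions chain within the layer
      if (i <= L - 1) {
        for (int d = -B; d < B; ++d) {
          int t = i + d;
          if (t < 1) continue;
          int pnext = e - t;           // target base the gap consumes
          if (pnext < 1 || tg[(size_t)(pnext - 1)] < 0) continue;
          for (int g = 0; g < NG; ++g)
            for (int nb = 0; nb < NB; ++nb)
              for (int ns = 0; ns < NS; ++ns) {
                size_t c = idx(i, d, g, nb, ns);
                if (stamp[c] != cur) continue;
                double v = val[c];
                int nb2 = nb, tt;
                double add;
                if (g == 2) { add = bulge_ext; tt = 4; }
                else { add = bulge_pen; nb2 = nb + 1; tt = 3; if (nb2 >= NB) continue; }
                double v2 = v + add;
                if (v2 > max_score + 1e-9) continue;
                relax(i, idx(i, d + 1, 2, nb2, ns), v2, nmm[c], tt, c);
              }
        }
      }
      if (i == L) break;

      for (int d = -B; d <= B; ++d) {
        int t = i + d;
        if (t < 1) continue;
        for (int g = 0; g < NG; ++g)
          for (int nb = 0; nb < NB; ++nb)
            for (int ns = 0; ns < NS; ++ns) {
              size_t c = idx(i, d, g, nb, ns);
              if (stamp[c] != cur) continue;
              double v = val[c];

              // pair sRNA position i+1 with target base e - t
              int pnext = e - t;
              if (pnext >= 1) {
                int pc = pair_code(s[(size_t)i], tg[(size_t)(pnext - 1)]);
                if (pc >= 0) {
                  int pos = i + 1, dm = 0, ns2 = ns;
                  double add = 0.0;
                  bool ok = true;
                  if (pc == 1) add = gu_pen;
                  else if (pc == 2) {
                    if (forb[(size_t)pos]) ok = false;
                    dm = 1;
                    if (pos >= seed_start && pos <= seed_end) {
                      ns2 = ns + 1; if (ns2 >= NS) ok = false; add = mm_seed;
                    } else add = mm_nonseed;
                  }
                  if (ok) {
                    double v2 = v + add;
                    if (v2 <= max_score + 1e-9)
                      relax(i + 1, idx(i + 1, d, 0, nb, ns2), v2, nmm[c] + dm, 0, c);
                  }
                }
              }

              // sRNA-side gap consuming sRNA position i+1 (internal only)
              int pos = i + 1;
              if (pos >= 2 && pos <= L - 1 && d - 1 >= -B) {
                int nb2 = nb, tt;
                double add;
                if (g == 1) { add = bulge_ext; tt = 2; }
                else { add = bulge_pen; nb2 = nb + 1; tt = 1; }
                if (nb2 < NB) {
                  double v2 = v + add;
                  if (v2 <= max_score + 1e-9)
                    relax(i + 1, idx(i + 1, d - 1, 1, nb2, ns), v2, nmm[c], tt, c);
                }
              }
            }
      }
    }

    // harvest layer L: last sRNA position paired, so gap state must be 0
    if (!layer_live[(size_t)L]) continue;
    for (int d = -B; d <= B; ++d) {
      int t = L + d;
      int start = e - t + 1;
      if (start < 1) continue;
      for (int nb = 0; nb < NB; ++nb)
        for (int ns = 0; ns < NS; ++ns) {
          size_t c = idx(L, d, 0, nb, ns);
          if (stamp[c] != cur) continue;
          double v = val[c];
          if (v > max_score + 1e-9) continue;
          auto it = winners.find(start);
          if (it != winners.end() &&
              !better(v, nb, nmm[c], it->second.pen, it->second.nb, it->second.nmm))
            continue;

          Hit h;
          h.start = start; h.end = e; h.pen = v; h.nb = nb; h.nmm = nmm[c];
          h.pairmap.assign((size_t)L, 0);
          h.states.assign((size_t)L, '?');
          std::vector<std::array<int, 2>> steps;   // (transition type, sRNA pos)
          size_t cur = c;
          int ci = L, ct = t;
          while (true) {
            int tt = ptype[cur];
            if (tt == 0) {
              int p = e - ct + 1;
              int pc = pair_code(s[(size_t)(ci - 1)], tg[(size_t)(p - 1)]);
              h.pairmap[(size_t)(ci - 1)] = p;
              h.states[(size_t)(ci - 1)] = (pc == 0 ? 'W' : (pc == 1 ? 'G' : 'M'));
              steps.push_back({0, ci});
              ci--; ct--;
            } else if (tt == 1 || tt == 2) {
              h.states[(size_t)(ci - 1)] = 'b';
              steps.push_back({tt, ci});
              ci--;
            } else {
              steps.push_back({tt, ci});
              ct--;
            }
            if (pprev[cur] < 0) break;
            cur = (size_t)pprev[cur];
          }
          std::reverse(steps.begin(), steps.end());  // now 5' -> 3'
          std::vector<std::array<int, 3>> events;    // side(1=S,2=T), pos, len
          for (auto& st : steps) {
            if (st[0] == 1) events.push_back({1, st[1], 1});
            else if (st[0] == 2) events.back()[2]++;
            else if (st[0] == 3) events.push_back({2, st[1], 1});
            else if (st[0] == 4) events.back()[2]++;
          }
          std::string bs;
          for (size_t k = 0; k < events.size(); ++k) {
            if (k) bs += ";";
            bs += (events[k][0] == 1 ? "S:" : "T:");
            bs += std::to_string(events[k][1]) + ":" + std::to_string(events[k][2]);
          }
          h.bulges = bs;
          winners[start] = h;
        }
    }
  }

  int n = (int)winners.size();
  IntegerVector rs(n), re(n), rnb(n), rnm(n);
  NumericVector rp(n);
  CharacterVector rst(n), rbl(n);
  List rpm_(n);
  int k = 0;
  for (auto& kv : winners) {
    rs[k] = kv.second.start; re[k] = kv.second.end;
    rp[k] = kv.second.pen; rnb[k] = kv.second.nb; rnm[k] = kv.second.nmm;
    rst[k] = kv.second.states; rbl[k] = kv.second.bulges;
    rpm_[k] = IntegerVector(kv.second.pairmap.begin(), kv.second.pairmap.end());
    ++k;
  }
  return List::create(_["target_start"] = rs, _["target_end"] = re,
                      _["penalty"] = rp, _["n_bulges"] = rnb,
                      _["n_mismatch"] = rnm, _["states"] = rst,
                      _["bulges"] = rbl, _["pairmap"] = rpm_);
}
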