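#include <Rcpp.h>
#include <unordered_map>
#include <string>
#include <vector>
#include <algorithm>

using namespace Rcpp;

// Hamming distance with early exit; unequal lengths -> INT_MAX sentinel.
static inline int hamming(const std::string& a, const std::string& b, int cap) {
  if (a.size() != b.size()) return INT_MAX;
  int d = 0;
  for (size_t i = 0; i < a.size(); ++i) {
    if (a[i] != b[i]) {
      if (++d > cap) return d;
    }
  }
  return d;
}

// [[Rcpp::export]]
IntegerVector cpp_hamming_to(CharacterVector seqs, std::string pattern) {
  int n = seqs.size();
  IntegerVector out(n);
  int plen = pattern.size();
  for (int i = 0; i < n; ++i) {
    const char* s = CHAR(STRING_ELT(seqs, i));
    int len = LENGTH(STRING_ELT(seqs, i));
    if (len != plen) { out[i] = NA_INTEGER; continue; }
    int d = 0;
    for (int j = 0; j < plen; ++j) if (s[j] != pattern[j]) ++d;
    out[i] = d;
  }
  return out;
}

// Minimum pairwise Hamming distance over a set of equal-length sequences.
// [[Rcpp::export]]
int cpp_min_pairwise_hamming(CharacterVector seqs) {
  int n = seqs.size();
  if (n < 2) return NA_INTEGER;
  std::vector<std::string> v(n);
  for (int i = 0; i < n; ++i) v[i] = as<std::string>(seqs[i]);
  int best = INT_MAX;
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      int d = hamming(v[i], v[j], best);
      if (d < best) best = d;
      if (best == 0) return 0;
    }
  }
  return best;
}

// Distances from one candidate to every accepted sequence, early-exit at cap.
// Used by whitelist rejection sampling: returns true if candidate is at
// distance >= min_dist from all accepted.
// [[Rcpp::export]]
bool cpp_all_at_distance(std::string candidate, CharacterVector accepted,
                         int min_dist) {
  int n = accepted.size();
  for (int i = 0; i < n; ++i) {
    std::string a = as<std::string>(accepted[i]);
    int d = hamming(candidate, a, min_dist);
    if (d < min_dist) return false;
  }
  return true;
}

// Whitelist assignment. Returns 1-based index of the assigned entry,
// 0 = unmatched, -1 = ambiguous (>=2 entries at the minimal distance
// <= max_mm). Exact matches win via hash lookup. 'N' never matches, so it
// counts as a mismatch automatically.
// [[Rcpp::export]]
IntegerVector cpp_match_whitelist(CharacterVector seqs, CharacterVector codes,
                                  int max_mm) {
  int n = seqs.size(), k = codes.size();
  std::vector<std::string> wl(k);
  std::unordered_map<std::string, int> exact;
  for (int i = 0; i < k; ++i) {
    wl[i] = as<std::string>(codes[i]);
    exact[wl[i]] = i + 1;
  }
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) {
    std::string s = as<std::string>(seqs[i]);
    auto it = exact.find(s);
    if (it != exact.end()) { out[i] = it->second; continue; }
    if (max_mm <= 0) { out[i] = 0; continue; }
    int best = INT_MAX, best_idx = 0, n_best = 0;
    for (int j = 0; j < k; ++j) {
      int d = hamming(s, wl[j], max_mm);
      if (d < best) { best = d; best_idx = j + 1; n_best = 1; }
      else if (d == best) ++n_best;
    }
    if (best > max_mm) out[i] = 0;
    else if (n_best > 1) out[i] = -1;
    else out[i] = best_idx;
  }
  return out;
}

// Directional UMI collapse (adjacency scheme): nodes are distinct UMIs with
// read counts; directed edge u -> v iff Hamming(u, v) == 1 and
// count(u) >= 2 * count(v) - 1. Nodes are visited in order of decreasing
// count (ties broken lexicographically); each unvisited node seeds a cluster
// and absorbs everything reachable through unvisited nodes. Returns the
// number of clusters (estimated molecules).
static int collapse_directional_core(const std::vector<std::string>& umis,
                                     const std::vector<double>& counts) {
  int n = umis.size();
  if (n == 0) return 0;
  if (n == 1) return 1;
  std::unordered_map<std::string, int> index;
  index.reserve(n * 2);
  for (int i = 0; i < n; ++i) index[umis[i]] = i;
  std::vector<int> order(n);
  for (int i = 0; i < n; ++i) order[i] = i;
  std::sort(order.begin(), order.end(), [&](int a, int b) {
    if (counts[a] != counts[b]) return counts[a] > counts[b];
    return umis[a] < umis[b];
  });
  std::vector<bool> visited(n, false);
  const char bases[4] = {'A', 'C', 'G', 'T'};
  int clusters = 0;
  std::vector<int> stack;
  for (int oi = 0; oi < n; ++oi) {
    int root = order[oi];
    if (visited[root]) continue;
    ++clusters;
    visited[root] = true;
    stack.clear();
    stack.push_back(root);
    while (!stack.empty()) {
      int u = stack.back();
      stack.pop_back();
      std::string neigh = umis[u];
      for (size_t p = 0; p < neigh.size(); ++p) {
        char orig = neigh[p];
        for (int b = 0; b < 4; ++b) {
          if (bases[b] == orig) continue;
          neigh[p] = bases[b];
          auto it = index.find(neigh);
          if (it != index.end()) {
            int v = it->second;
            if (!visited[v] && counts[u] >= 2.0 * counts[v] - 1.0) {
              visited[v] = true;
              stack.push_back(v);
            }
          }
        }
        neigh[p] = orig;
      }
    }
  }
  return clusters;
}

// [[Rcpp::export]]
int cpp_collapse_directional(CharacterVector umis, NumericVector counts) {
  int n = umis.size();
  std::vector<std::string> u(n);
  std::vector<double> c(n);
  for (int i = 0; i < n; ++i) {
    u[i] = as<std::string>(umis[i]);
    c[i] = counts[i];
  }
  return collapse_directional_core(u, c);
}

// Grouped deduplication: reads carry a 1-based barcode index (0 = skip) and
// a UMI string. Counts reads per (barcode, UMI), then collapses UMIs per
// barcode. Returns a list with per-barcode molecule counts for both the
// directional and the unique method, plus assigned read counts.
// [[Rcpp::export]]
List cpp_dedup_by_barcode(IntegerVector barcode_idx, CharacterVector umis,
                          int n_barcodes) {
  std::vector<std::unordered_map<std::string, double>> tab(n_barcodes);
  int n = barcode_idx.size();
  IntegerVector reads_per_bc(n_barcodes);
  for (int i = 0; i < n; ++i) {
    int b = barcode_idx[i];
    if (b < 1 || b > n_barcodes) continue;
    const char* u = CHAR(STRING_ELT(umis, i));
    int ulen = LENGTH(STRING_ELT(umis, i));
    bool has_n = false;
    for (int j = 0; j < ulen; ++j) {
      char ch = u[j];
      if (ch != 'A' && ch != 'C' && ch != 'G' && ch != 'T') { has_n = true; break; }
    }
    reads_per_bc[b - 1] += 1;
    if (has_n) continue;  // UMIs with ambiguous bases dropped before collapse
    tab[b - 1][std::string(u, ulen)] += 1.0;
  }
  IntegerVector directional(n_barcodes), unique_(n_barcodes);
  for (int b = 0; b < n_barcodes; ++b) {
    int m = tab[b].size();
    unique_[b] = m;
    std::vector<std::string> u;
    std::vector<double> c;
    u.reserve(m); c.reserve(m);
    for (auto& kv : tab[b]) { u.push_back(kv.first); c.push_back(kv.second); }
    directional[b] = collapse_directional_core(u, c);
  }
  return List::create(_["directional"] = directional,
                      _["unique"] = unique_,
                      _["reads"] = reads_per_bc);
}

// Encode non-negative integers < 4^len as DNA strings (base-4, A=0, C=1,
// G=2, T=3, most significant position first).
// [[Rcpp::export]]
CharacterVector cpp_int_to_dna(NumericVector ints, int len) {
  int n = ints.size();
  const char bases[4] = {'A', 'C', 'G', 'T'};
  CharacterVector out(n);
  std::string buf(len, 'A');
  for (int i = 0; i < n; ++i) {
    double x = ints[i];
    for (int p = len - 1; p >= 0; --p) {
      double q = std::floor(x / 4.0);
      int digit = (int)(x - 4.0 * q);
      buf[p] = bases[digit];
      x = q;
    }
    SET_STRING_ELT(out, i, Rf_mkCharLen(buf.c_str(), len));
  }
  return out;
}

// In-place-style substitution mutator: for error event e, read read_idx[e]
// (1-based) gets base new_base[e] written at position pos[e] (1-based).
// Returns a new vector; untouched reads share the input CHARSXPs.
// [[Rcpp::export]]
CharacterVector cpp_apply_substitutions(CharacterVector reads,
                                        IntegerVector read_idx,
                                        IntegerVector pos,
                                        CharacterVector new_base) {
  CharacterVector out = clone(reads);
  int ne = read_idx.size();
  for (int e = 0; e < ne; ++e) {
    int i = read_idx[e] - 1;
    std::string s = as<std::string>(out[i]);
    int p = pos[e] - 1;
    if (p >= 0 && p < (int)s.size()) {
      s[p] = as<std::string>(new_base[e])[0];
      out[i] = s;
    }
  }
  return out;
}

// Assemble reads for one sample: read i of molecule m is
// prefix + barcode(bc_of_mol[m]) + umi_of_mol[m] + suffix, with substitution
// errors applied in-line. Error events must be sorted by err_read (1-based
// read index in assembly order); err_shift in 1..3 rotates the original
// base within ACGT.
// [[Rcpp::export]]
CharacterVector cpp_assemble_reads(std::string prefix, CharacterVector bc_seqs,
                                   IntegerVector bc_of_mol,
                                   CharacterVector umi_of_mol,
                                   IntegerVector reads_per_mol,
                                   std::string suffix,
                                   IntegerVector err_read,
                                   IntegerVector err_pos,
                                   IntegerVector err_shift) {
  int n_mol = bc_of_mol.size();
  long n_reads = 0;
  for (int m = 0; m < n_mol; ++m) n_reads += reads_per_mol[m];
  CharacterVector out(n_reads);
  int n_err = err_read.size();
  int e = 0;
  long r = 0;
  std::string buf;
  const char bases[4] = {'A', 'C', 'G', 'T'};
  for (int m = 0; m < n_mol; ++m) {
    int k = reads_per_mol[m];
    if (k == 0) continue;
    const char* bc = CHAR(STRING_ELT(bc_seqs, bc_of_mol[m] - 1));
    const char* umi = CHAR(STRING_ELT(umi_of_mol, m));
    std::string templ = prefix;
    templ += bc;
    templ += umi;
    templ += suffix;
    SEXP templ_sexp = R_NilValue;  // shared CHARSXP for error-free copies
    for (int i = 0; i < k; ++i, ++r) {
      if (e < n_err && (long)err_read[e] - 1 == r) {
        buf = templ;
        while (e < n_err && (long)err_read[e] - 1 == r) {
          int p = err_pos[e] - 1;
          if (p >= 0 && p < (int)buf.size()) {
            int bi = 0;
            switch (buf[p]) {
              case 'A': bi = 0; break; case 'C': bi = 1; break;
              case 'G': bi = 2; break; default: bi = 3; break;
            }
            buf[p] = bases[(bi + err_shift[e]) % 4];
          }
          ++e;
        }
        SET_STRING_ELT(out, r, Rf_mkCharLen(buf.c_str(), buf.size()));
      } else {
        if (templ_sexp == R_NilValue) {
          templ_sexp = Rf_mkCharLen(templ.c_str(), templ.size());
        }
        SET_STRING_ELT(out, r, templ_sexp);
      }
    }
  }
  return out;
}

// One-pass per-sample quantification: anchor check, positional extraction,
// whitelist assignment and per-barcode UMI deduplication. Returns per-
// barcode molecule counts (directional + unique) and the read-fate QC
// counters. Layout: barcode at [prefix_len, prefix_len + bc_len), UMI
// immediately after.
// [[Rcpp::export]]
List cpp_quantify_sample(CharacterVector reads, std::string prefix_seq,
                         int anchor_max_mm, CharacterVector codes,
                         int max_mm, int bc_len, int umi_len, int total_len) {
  int k = codes.size();
  std::vector<std::string> wl(k);
  std::unordered_map<std::string, int> exact;
  for (int i = 0; i < k; ++i) {
    wl[i] = as<std::string>(codes[i]);
    exact[wl[i]] = i + 1;
  }
  int plen = prefix_seq.size();
  long n = reads.size();
  long anchor_fail = 0, unmatched = 0, ambiguous = 0, assigned = 0;
  std::vector<std::unordered_map<std::string, double>> tab(k);
  IntegerVector reads_per_bc(k);
  std::string bc_buf(bc_len, 'N');
  for (long i = 0; i < n; ++i) {
    const char* s = CHAR(STRING_ELT(reads, i));
    int len = LENGTH(STRING_ELT(reads, i));
    if (len < total_len) { ++anchor_fail; continue; }
    int mm = 0;
    for (int j = 0; j < plen; ++j) {
      if (s[j] != prefix_seq[j] && ++mm > anchor_max_mm) break;
    }
    if (mm > anchor_max_mm) { ++anchor_fail; continue; }
    bc_buf.assign(s + plen, bc_len);
    int idx = 0;
    auto it = exact.find(bc_buf);
    if (it != exact.end()) {
      idx = it->second;
    } else if (max_mm > 0) {
      int best = INT_MAX, best_idx = 0, n_best = 0;
      for (int j = 0; j < k; ++j) {
        int d = hamming(bc_buf, wl[j], max_mm);
        if (d < best) { best = d; best_idx = j + 1; n_best = 1; }
        else if (d == best) ++n_best;
      }
      if (best > max_mm) idx = 0;
      else if (n_best > 1) idx = -1;
      else idx = best_idx;
    }
    if (idx == 0) { ++unmatched; continue; }
    if (idx == -1) { ++ambiguous; continue; }
    ++assigned;
    reads_per_bc[idx - 1] += 1;
    const char* u = s + plen + bc_len;
    bool has_n = false;
    for (int j = 0; j < umi_len; ++j) {
      char ch = u[j];
      if (ch != 'A' && ch != 'C' && ch != 'G' && ch != 'T') { has_n = true; break; }
    }
    if (has_n) continue;
    tab[idx - 1][std::string(u, umi_len)] += 1.0;
  }
  IntegerVector directional(k), unique_(k);
  for (int b = 0; b < k; ++b) {
    int m = tab[b].size();
    unique_[b] = m;
    std::vector<std::string> u;
    std::vector<double> c;
    u.reserve(m); c.reserve(m);
    for (auto& kv : tab[b]) { u.push_back(kv.first); c.push_back(kv.second); }
    directional[b] = collapse_directional_core(u, c);
  }
  return List::create(_["directional"] = directional,
                      _["unique"] = unique_,
                      _["reads"] = reads_per_bc,
                      _["reads_in"] = (double)n,
                      _["anchor_fail"] = (double)anchor_fail,
                      _["unmatched"] = (double)unmatched,
                      _["ambiguous"] = (double)ambiguous,
                      _["assigned"] = (double)assigned);
}

// Branching PCR: every copy of every molecule duplicates independently with
// probability eff in each of `cycles` rounds. Exact binomial draws for small
// copy numbers; for large sizes (variance > 1e4) the binomial increment is
// drawn from its normal approximation, clamped to [0, X] -- at those sizes
// the relative error is negligible and unobservable after depth subsampling.
// Uses R's RNG stream (deterministic under set.seed()).
// [[Rcpp::export]]
NumericVector cpp_pcr_copies(int n_mol, int cycles, double eff) {
  NumericVector copies(n_mol, 1.0);
  if (cycles <= 0 || eff <= 0.0) return copies;
  GetRNGstate();
  for (int m = 0; m < n_mol; ++m) {
    double x = 1.0;
    for (int c = 0; c < cycles; ++c) {
      double inc;
      if (eff >= 1.0) {
        inc = x;
      } else if (x * eff * (1.0 - eff) > 25.0) {
        inc = R::rnorm(x * eff, std::sqrt(x * eff * (1.0 - eff)));
        inc = std::floor(inc + 0.5);
        if (inc < 0.0) inc = 0.0;
        if (inc > x) inc = x;
      } else {
        inc = R::rbinom(x, eff);
      }
      x += inc;
    }
    copies[m] = x;
  }
  PutRNGstate();
  return copies;
}

// Fused per-sample simulate + quantify: builds each read's bytes in a
// scratch buffer (identical to cpp_assemble_reads output) and feeds it
// straight through the anchor / whitelist / UMI-dedup logic of
// cpp_quantify_sample without creating R strings. All randomness (UMIs,
// PCR copy numbers, depth sampling, error events) is drawn by the caller,
// so the result is bit-identical to assembling reads and quantifying them.
// [[Rcpp::export]]
List cpp_sim_quant_sample(std::string prefix, CharacterVector bc_seqs,
                          IntegerVector bc_of_mol, NumericVector umi_int,
                          IntegerVector reads_per_mol, std::string suffix,
                          IntegerVector err_read, IntegerVector err_pos,
                          IntegerVector err_shift, int umi_len,
                          int anchor_max_mm, int max_mm) {
  int k = bc_seqs.size();
  std::vector<std::string> wl(k);
  std::unordered_map<std::string, int> exact;
  for (int i = 0; i < k; ++i) {
    wl[i] = as<std::string>(bc_seqs[i]);
    exact[wl[i]] = i + 1;
  }
  int bc_len = k > 0 ? wl[0].size() : 0;
  int plen = prefix.size();
  int total_len = plen + bc_len + umi_len + (int)suffix.size();
  const char bases[4] = {'A', 'C', 'G', 'T'};

  long anchor_fail = 0, unmatched = 0, ambiguous = 0, assigned = 0;
  long n_reads_total = 0;
  std::vector<std::unordered_map<std::string, double>> tab(k);
  IntegerVector reads_per_bc(k);
  std::string bc_buf(bc_len > 0 ? bc_len : 1, 'N');

  int n_mol = bc_of_mol.size();
  int n_err = err_read.size();
  int e = 0;
  long r = 0;
  std::string templ, buf, umi_str(umi_len, 'A');
  for (int m = 0; m < n_mol; ++m) {
    int kk = reads_per_mol[m];
    if (kk == 0) continue;
    double x = umi_int[m];
    for (int p = umi_len - 1; p >= 0; --p) {
      double q = std::floor(x / 4.0);
      umi_str[p] = bases[(int)(x - 4.0 * q)];
      x = q;
    }
    templ = prefix;
    templ += wl[bc_of_mol[m] - 1];
    templ += umi_str;
    templ += suffix;
    for (int i = 0; i < kk; ++i, ++r) {
      const std::string* read = &templ;
      if (e < n_err && (long)err_read[e] - 1 == r) {
        buf = templ;
        while (e < n_err && (long)err_read[e] - 1 == r) {
          int p = err_pos[e] - 1;
          if (p >= 0 && p < (int)buf.size()) {
            int bi = 0;
            switch (buf[p]) {
              case 'A': bi = 0; break; case 'C': bi = 1; break;
              case 'G': bi = 2; break; default: bi = 3; break;
            }
            buf[p] = bases[(bi + err_shift[e]) % 4];
          }
          ++e;
        }
        read = &buf;
      }
      ++n_reads_total;
      const char* s = read->c_str();
      if ((int)read->size() < total_len) { ++anchor_fail; continue; }
      int mm = 0;
      for (int j = 0; j < plen; ++j) {
        if (s[j] != prefix[j] && ++mm > anchor_max_mm) break;
      }
      if (mm > anchor_max_mm) { ++anchor_fail; continue; }
      bc_buf.assign(s + plen, bc_len);
      int idx = 0;
      auto it = exact.find(bc_buf);
      if (it != exact.end()) {
        idx = it->second;
      } else if (max_mm > 0) {
        int best = INT_MAX, best_idx = 0, n_best = 0;
        for (int j = 0; j < k; ++j) {
          int d = hamming(bc_buf, wl[j], max_mm);
          if (d < best) { best = d; best_idx = j + 1; n_best = 1; }
          else if (d == best) ++n_best;
        }
        if (best > max_mm) idx = 0;
        else if (n_best > 1) idx = -1;
        else idx = best_idx;
      }
      if (idx == 0) { ++unmatched; continue; }
      if (idx == -1) { ++ambiguous; continue; }
      ++assigned;
      reads_per_bc[idx - 1] += 1;
      const char* u = s + plen + bc_len;
      bool has_n = false;
      for (int j = 0; j < umi_len; ++j) {
        char ch = u[j];
        if (ch != 'A' && ch != 'C' && ch != 'G' && ch != 'T') {
          has_n = true; break;
        }
      }
      if (has_n) continue;
      tab[idx - 1][std::string(u, umi_len)] += 1.0;
    }
  }
  IntegerVector directional(k), unique_(k);
  for (int b = 0; b < k; ++b) {
    int m = tab[b].size();
    unique_[b] = m;
    std::vector<std::string> u;
    std::vector<double> c;
    u.reserve(m); c.reserve(m);
    for (auto& kv : tab[b]) { u.push_back(kv.first); c.push_back(kv.second); }
    directional[b] = collapse_directional_core(u, c);
  }
  return List::create(_["directional"] = directional,
                      _["unique"] = unique_,
                      _["reads"] = reads_per_bc,
                      _["reads_in"] = (double)n_reads_total,
                      _["anchor_fail"] = (double)anchor_fail,
                      _["unmatched"] = (double)unmatched,
                      _["ambiguous"] = (double)ambiguous,
                      _["assigned"] = (double)assigned);
}

// Continue branching PCR from per-molecule start states for `cycles` more
// rounds (same exact-binomial / clamped-normal hybrid as cpp_pcr_copies).
// [[Rcpp::export]]
NumericVector cpp_pcr_copies_from(IntegerVector start, int cycles,
                                  double eff) {
  int n = start.size();
  NumericVector copies(n);
  GetRNGstate();
  for (int m = 0; m < n; ++m) {
    double x = start[m];
    for (int c = 0; c < cycles; ++c) {
      double inc;
      if (eff >= 1.0) {
        inc = x;
      } else if (x * eff * (1.0 - eff) > 25.0) {
        inc = R::rnorm(x * eff, std::sqrt(x * eff * (1.0 - eff)));
        inc = std::floor(inc + 0.5);
        if (inc < 0.0) inc = 0.0;
        if (inc > x) inc = x;
      } else {
        inc = R::rbinom(x, eff);
      }
      x += inc;
    }
    copies[m] = x;
  }
  PutRNGstate();
  return copies;
}
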