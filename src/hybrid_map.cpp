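#include <Rcpp.h>
#include <unordered_map>
#include <string>
#include <vector>
using namespace Rcpp;

// Locate the best full-length occurrence of any miRNA pattern in each read.
// Patterns are searched exactly (max_mm == 0, substring search) or with up to
// max_mm mismatches (naive scan with early exit). Best = fewest mismatches,
// ties broken by leftmost position then pattern order. second_disjoint
// reports whether another (non-overlapping) occurrence exists.
// [[Rcpp::export]]
List cpp_find_arms(CharacterVector reads, CharacterVector patterns, int max_mm) {
  const int n = reads.size(), np = patterns.size();
  std::vector<std::string> pats(np);
  for (int p = 0; p < np; ++p) pats[p] = as<std::string>(patterns[p]);
  IntegerVector arm(n, 0), start(n, NA_INTEGER), mism(n, NA_INTEGER);
  LogicalVector second(n, false);

  for (int r = 0; r < n; ++r) {
    std::string s = as<std::string>(reads[r]);
    const int L = (int)s.size();
    int best_p = -1, best_pos = -1, best_mm = max_mm + 1;
    // collect all occurrences (pos, end) with mm <= max_mm
    std::vector<std::pair<int,int> > occ;
    for (int p = 0; p < np; ++p) {
      const std::string &pat = pats[p];
      const int pl = (int)pat.size();
      if (pl > L) continue;
      if (max_mm == 0) {
        size_t pos = s.find(pat, 0);
        while (pos != std::string::npos) {
          occ.push_back(std::make_pair((int)pos, (int)pos + pl));
          if (best_p < 0 || (int)pos < best_pos) {
            best_p = p; best_pos = (int)pos; best_mm = 0;
          }
          pos = s.find(pat, pos + 1);
        }
      } else {
        for (int pos = 0; pos + pl <= L; ++pos) {
          int mm = 0;
          for (int i = 0; i < pl; ++i) {
            if (s[pos + i] != pat[i]) { if (++mm > max_mm) break; }
          }
          if (mm <= max_mm) {
            occ.push_back(std::make_pair(pos, pos + pl));
            if (mm < best_mm || (mm == best_mm && pos < best_pos)) {
              best_p = p; best_pos = pos; best_mm = mm;
            }
          }
        }
      }
    }
    if (best_p >= 0) {
      arm[r] = best_p + 1;
      start[r] = best_pos;
      mism[r] = best_mm == max_mm + 1 ? 0 : best_mm;
      const int bend = best_pos + (int)pats[best_p].size();
      for (size_t q = 0; q < occ.size(); ++q) {
        if (occ[q].second <= best_pos || occ[q].first >= bend) {
          second[r] = true; break;
        }
      }
    }
  }
  return List::create(_["pattern"] = arm, _["start"] = start,
                      _["mismatches"] = mism, _["second_disjoint"] = second);
}

// Map target flanks onto a transcriptome by exact k-mer seeding plus ungapped
// extension. Seeds are taken at the flank start, middle and end; every seeded
// locus is scored by its number of matching bases over the full flank length.
// Returns the best locus, its match count and the runner-up match count
// (0 when there is no second candidate locus).
// [[Rcpp::export]]
List cpp_map_flanks(CharacterVector flanks, CharacterVector tx_seqs, int k) {
  const int nt = tx_seqs.size();
  std::vector<std::string> txs(nt);
  std::unordered_map<std::string, std::vector<std::pair<int,int> > > index;
  for (int t = 0; t < nt; ++t) {
    txs[t] = as<std::string>(tx_seqs[t]);
    const int L = (int)txs[t].size();
    for (int p = 0; p + k <= L; ++p) {
      index[txs[t].substr(p, k)].push_back(std::make_pair(t, p));
    }
  }

  const int n = flanks.size();
  IntegerVector tx(n, 0), start(n, NA_INTEGER), best(n, 0), second(n, 0);
  for (int r = 0; r < n; ++r) {
    std::string f = as<std::string>(flanks[r]);
    const int fl = (int)f.size();
    if (fl < k) continue;
    std::vector<std::pair<int,int> > cands;
    int qpos[3] = {0, (fl - k) / 2, fl - k};
    for (int qi = 0; qi < 3; ++qi) {
      int q = qpos[qi];
      if (qi > 0 && q == qpos[qi - 1]) continue;
      std::unordered_map<std::string, std::vector<std::pair<int,int> > >::iterator
        it = index.find(f.substr(q, k));
      if (it == index.end()) continue;
      for (size_t h = 0; h < it->second.size(); ++h) {
        int t = it->second[h].first;
        int st = it->second[h].second - q;
        if (st < 0 || st + fl > (int)txs[t].size()) continue;
        bool seen = false;
        for (size_t c = 0; c < cands.size(); ++c) {
          if (cands[c].first == t && cands[c].second == st) { seen = true; break; }
        }
        if (!seen) cands.push_back(std::make_pair(t, st));
      }
    }
    int b1 = 0, b2 = 0, bt = -1, bs = -1;
    for (size_t c = 0; c < cands.size(); ++c) {
      const std::string &ts = txs[cands[c].first];
      int matches = 0;
      for (int i = 0; i < fl; ++i) {
        if (ts[cands[c].second + i] == f[i]) ++matches;
      }
      if (matches > b1) {
        b2 = b1; b1 = matches; bt = cands[c].first; bs = cands[c].second;
      } else if (matches > b2) {
        b2 = matches;
      }
    }
    if (bt >= 0) { tx[r] = bt + 1; start[r] = bs; best[r] = b1; second[r] = b2; }
  }
  return List::create(_["tx"] = tx, _["start"] = start,
                      _["best_matches"] = best, _["second_matches"] = second);
}

// Full hybrid detection in one pass: arm search, flank choice, k-mer target
// mapping and status assignment. Status codes: 1 accepted, 2 no_mirna_arm,
// 3 multiple_mirna_arms, 4 target_too_short, 5 ambiguous_target.
// [[Rcpp::export]]
List cpp_detect(CharacterVector reads, CharacterVector patterns,
                CharacterVector tx_seqs, int max_mm, int min_target_len,
                int k) {
  const int nt = tx_seqs.size(), np = patterns.size();
  std::vector<std::string> txs(nt), pats(np);
  for (int p = 0; p < np; ++p) pats[p] = as<std::string>(patterns[p]);
  std::unordered_map<std::string, std::vector<std::pair<int,int> > > index;
  for (int t = 0; t < nt; ++t) {
    txs[t] = as<std::string>(tx_seqs[t]);
    const int L = (int)txs[t].size();
    for (int p = 0; p + k <= L; ++p)
      index[txs[t].substr(p, k)].push_back(std::make_pair(t, p));
  }

  const int n = reads.size();
  IntegerVector status(n, 2), arm(n, NA_INTEGER), astart(n, NA_INTEGER),
    aend(n, NA_INTEGER), tx(n, NA_INTEGER), tstart(n, NA_INTEGER),
    tend(n, NA_INTEGER), order(n, NA_INTEGER);

  // map one flank; returns matches of best locus, fills t/pos, and whether
  // the locus is unique (margin >= 2 over runner-up, near-exact match)
  struct MapRes { int tx, pos, best, second; bool ok; };

  for (int r = 0; r < n; ++r) {
    std::string s = as<std::string>(reads[r]);
    const int L = (int)s.size();
    int best_p = -1, best_pos = -1, best_mm = max_mm + 1;
    std::vector<std::pair<int,int> > occ;
    for (int p = 0; p < np; ++p) {
      const std::string &pat = pats[p];
      const int pl = (int)pat.size();
      if (pl > L) continue;
      if (max_mm == 0) {
        size_t pos = s.find(pat, 0);
        while (pos != std::string::npos) {
          occ.push_back(std::make_pair((int)pos, (int)pos + pl));
          if (best_p < 0 || (int)pos < best_pos) {
            best_p = p; best_pos = (int)pos; best_mm = 0;
          }
          pos = s.find(pat, pos + 1);
        }
      } else {
        for (int pos = 0; pos + pl <= L; ++pos) {
          int mm = 0;
          for (int i = 0; i < pl; ++i)
            if (s[pos + i] != pat[i]) { if (++mm > max_mm) break; }
          if (mm <= max_mm) {
            occ.push_back(std::make_pair(pos, pos + pl));
            if (mm < best_mm || (mm == best_mm && pos < best_pos)) {
              best_p = p; best_pos = pos; best_mm = mm;
            }
          }
        }
      }
    }
    if (best_p < 0) { status[r] = 2; continue; }
    const int alen = (int)pats[best_p].size();
    const int bend = best_pos + alen;
    bool multi = false;
    for (size_t q = 0; q < occ.size(); ++q)
      if (occ[q].second <= best_pos || occ[q].first >= bend) { multi = true; break; }
    arm[r] = best_p + 1; astart[r] = best_pos; aend[r] = bend;
    if (multi) { status[r] = 3; continue; }

    const int llen = best_pos, rlen = L - bend;
    bool l_ok = llen >= min_target_len, r_ok = rlen >= min_target_len;
    if (!l_ok && !r_ok) { status[r] = 4; continue; }

    MapRes res[2]; bool tried[2] = {false, false};
    for (int side = 0; side < 2; ++side) {
      bool use = side == 0 ? l_ok : r_ok;
      if (!use) continue;
      tried[side] = true;
      const int fstart = side == 0 ? 0 : bend;
      const int fl = side == 0 ? llen : rlen;
      std::string f = s.substr(fstart, fl);
      std::vector<std::pair<int,int> > cands;
      int qpos[3] = {0, (fl - k) / 2, fl - k};
      for (int qi = 0; qi < 3; ++qi) {
        int q = qpos[qi];
        if (q < 0) continue;
        if (qi > 0 && q == qpos[qi - 1]) continue;
        std::unordered_map<std::string, std::vector<std::pair<int,int> > >::iterator
          it = index.find(f.substr(q, k));
        if (it == index.end()) continue;
        for (size_t h = 0; h < it->second.size(); ++h) {
          int t = it->second[h].first;
          int st = it->second[h].second - q;
          if (st < 0 || st + fl > (int)txs[t].size()) continue;
          bool seen = false;
          for (size_t c = 0; c < cands.size(); ++c)
            if (cands[c].first == t && cands[c].second == st) { seen = true; break; }
          if (!seen) cands.push_back(std::make_pair(t, st));
        }
      }
      int b1 = 0, b2 = 0, bt = -1, bs = -1;
      for (size_t c = 0; c < cands.size(); ++c) {
        const std::string &ts = txs[cands[c].first];
        int matches = 0;
        for (int i = 0; i < fl; ++i)
          if (ts[cands[c].second + i] == f[i]) ++matches;
        if (matches > b1) { b2 = b1; b1 = matches; bt = cands[c].first; bs = cands[c].second; }
        else if (matches > b2) b2 = matches;
      }
      res[side].tx = bt; res[side].pos = bs; res[side].best = b1;
      res[side].second = b2;
      res[side].ok = bt >= 0 && (b1 - b2) >= 2 && b1 >= fl - 2;
    }
    bool useR = tried[1] && res[1].ok &&
      (!(tried[0] && res[0].ok) || res[1].best >= res[0].best);
    bool useL = !useR && tried[0] && res[0].ok;
    if (!useL && !useR) { status[r] = 5; continue; }
    const int side = useR ? 1 : 0;
    const int fl = side == 0 ? llen : rlen;
    status[r] = 1; tx[r] = res[side].tx + 1; tstart[r] = res[side].pos;
    tend[r] = res[side].pos + fl; order[r] = side == 1 ? 1 : 2;
  }
  return List::create(_["status"] = status, _["pattern"] = arm,
                      _["mirna_start"] = astart, _["mirna_end"] = aend,
                      _["tx"] = tx, _["target_start"] = tstart,
                      _["target_end"] = tend, _["arm_order"] = order);
}

// Collapse exact duplicate strings, preserving first-occurrence order.
// Returns 1-based indices of the representatives and their multiplicities.
// [[Rcpp::export]]
List cpp_collapse(CharacterVector x) {
  const int n = x.size();
  std::unordered_map<std::string, int> seen;
  seen.reserve((size_t)n * 2);
  std::vector<int> keep; keep.reserve(n);
  std::vector<int> mult; mult.reserve(n);
  for (int i = 0; i < n; ++i) {
    std::string s = as<std::string>(x[i]);
    std::unordered_map<std::string, int>::iterator it = seen.find(s);
    if (it == seen.end()) {
      seen.insert(std::make_pair(s, (int)keep.size()));
      keep.push_back(i + 1);
      mult.push_back(1);
    } else {
      ++mult[it->second];
    }
  }
  return List::create(_["keep"] = wrap(keep), _["multiplicity"] = wrap(mult));
}
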