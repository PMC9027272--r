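#ifndef RPSIM_RNG_H
#define RPSIM_RNG_H

#include <cstdint>
#include <cmath>

// Minimal PCG32 (O'Neill's permuted congruential generator, XSH-RR output).
// Self-contained so that million-step lattice/agent runs are reproducible
// from a single integer seed and cheap enough for ~1e10 draws.
class Pcg32 {
public:
    explicit Pcg32(std::uint64_t seed, std::uint64_t stream = 54u) {
        state_ = 0u;
        inc_ = (stream << 1u) | 1u;
        next();
        state_ += 0x853c49e6748fea9bULL + seed;
        next();
        have_spare_ = false;
        spare_ = 0.0;
    }

    std::uint32_t next() {
        std::uint64_t old = state_;
        state_ = old * 6364136223846793005ULL + inc_;
        std::uint32_t xorshifted =
            static_cast<std::uint32_t>(((old >> 18u) ^ old) >> 27u);
        std::uint32_t rot = static_cast<std::uint32_t>(old >> 59u);
        return (xorshifted >> rot) | (xorshifted << ((-rot) & 31u));
    }

    // uniform on [0, 1)
    double runif() {
        return next() * (1.0 / 4294967296.0);
    }

    // uniform on (0, 1]  (needed for -log(x) lifetime sampling)
    double runif_pos() {
        return (static_cast<double>(next()) + 1.0) * (1.0 / 4294967296.0);
    }

    // standard normal, Marsaglia polar method with one cached deviate
    double rnorm() {
        if (have_spare_) {
            have_spare_ = false;
            return spare_;
        }
        double u, v, s;
        do {
            u = 2.0 * runif() - 1.0;
            v = 2.0 * runif() - 1.0;
            s = u * u + v * v;
        } while (s >= 1.0 || s == 0.0);
        double f = std::sqrt(-2.0 * std::log(s) / s);
        spare_ = v * f;
        have_spare_ = true;
        return u * f;
    }

    // Fisher-Yates shuffle of an index array
    template <typename T>
    void shuffle(T* v, int n) {
        for (int i = n - 1; i > 0; --i) {
            int j = static_cast<int>(next() % static_cast<std::uint32_t>(i + 1));
            T tmp = v[i]; v[i] = v[j]; v[j] = tmp;
        }
    }

private:
    std::uint64_t state_, inc_;
    bool have_spare_;
    double spare_;
};

#endif
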