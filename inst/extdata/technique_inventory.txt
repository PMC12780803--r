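# Default inventory of child-appealing marketing technique codes,
# one per line; extend with your coding scheme's codes.
character_licensed   # licensed media characters
character_brand      # brand mascots / spokes-characters
game_activity        # games, puzzles, activities on pack
fun_shape            # unusual product or package shapes
fun_colour           # unusual colours
child_font           # playful typography
cartoon_graphics     # cartoon-style artwork
child_language       # language addressed to children
premium_offer        # toys, collectibles, giveaways
movie_tiein          # film / show tie-ins
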